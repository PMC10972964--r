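# Sequence primitives: IUPAC-aware matching, reverse complement, translation,
# and FASTA/GFF3 I/O. All coordinates handed to users are 1-based inclusive
# (GRanges convention); within-gene anchor offsets (AnchorSet) are 0-based.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Match a degenerate IUPAC pattern against an equal-length DNA window
#'
#' Each pattern position is expanded to its IUPAC degeneracy set (e.g. `Y =
#' {C,T}`, `R = {A,G}`, `B = {C,G,T}`, `D = {A,G,T}`, `N = {A,C,G,T}`) and the
#' window base must fall in that set. Window bases outside `A/C/G/T` --
#' including `N`, as found in assembly gaps -- never satisfy any pattern
#' position, so candidate motifs are never called inside gaps.
#'
#' @param pattern IUPAC pattern string.
#' @param window DNA string of the same length, plain `A/C/G/T`.
#' @return `TRUE` iff every window base is in the degeneracy set of the
#'   corresponding pattern code.
#' @examples
#' matchIupac("TTYGGNNNNGG", "TTCGGAAAAGG")
#' matchIupac("CAC", "CAT")
#' @export
matchIupac <- function(pattern, window) {
  stopifnot(is.character(pattern), length(pattern) == 1L,
            is.character(window), length(window) == 1L)
  pattern <- toupper(pattern)
  window <- toupper(window)
  if (nchar(pattern) != nchar(window))
    stop("pattern and window must have equal length (", nchar(pattern),
         " vs ", nchar(window), ")")
  if (nchar(pattern) == 0L) return(TRUE)
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  bad <- !p %in% names(IUPAC_SETS)
  if (any(bad))
    stop("invalid IUPAC code '", p[which(bad)[1L]], "' at pattern position ",
         which(bad)[1L])
  all(vapply(seq_along(p), function(i) {
    w[i] %in% c("A", "C", "G", "T") && w[i] %in% IUPAC_SETS[[p[i]]]
  }, logical(1L)))
}

# All 1-based start positions in `seq` where `pattern` matches under
# matchIupac() semantics (overlapping matches included; windows containing
# non-ACGT characters never match, so pattern N does not match subject N).
scanIupac <- function(pattern, seq) {
  n <- nchar(seq)
  L <- nchar(pattern)
  if (n < L) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    allowed <- intersect(IUPAC_SETS[[pat[k]]], c("A", "C", "G", "T"))
    ok <- ok & chars[k:(n - L + k)] %in% allowed
  }
  which(ok)
}

#' Reverse complement of DNA strings with IUPAC support
#'
#' IUPAC codes are complemented to their partner code (`Y -> R`, `B -> V`,
#' ...), so the operation is an involution on any valid input. Vectorised.
#'
#' @param seq character vector of DNA strings (may be empty strings).
#' @return character vector of reverse complements.
#' @examples
#' revComp("CAC")
#' revComp("TTYGG")
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq))
  if (length(seq) == 0L) return(character(0))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTMRWSYKVHDBN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid DNA character '", substr(seq[i], bad[i], bad[i]),
         "' at position ", bad[i], " of sequence ", i)
  }
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Translate DNA in a given reading frame
#'
#' Standard genetic code; the trailing partial codon is dropped and codons
#' containing ambiguity codes translate to `X`. Stop codons are reported
#' as `*`.
#'
#' @param seq DNA string.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return amino-acid string (possibly empty).
#' @examples
#' translateDNA("CAGGTGCAGCAG")
#' translateDNA("TAA")
#' @export
translateDNA <- function(seq, frame = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L, frame %in% 0:2)
  seq <- toupper(seq)
  seq <- substr(seq, frame + 1L, nchar(seq))
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  codons <- substring(seq, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- GENCODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

GENCODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Read a FASTA file into a named DNAStringSet
#'
#' Sequence ids (first whitespace-delimited token of each header) must be
#' unique within the file; the remainder of the header is kept in the
#' `description` metadata column. Sequences are uppercased (soft-masking is
#' ignored).
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet] named by sequence id.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && !startsWith(first, ">"))
    stop("malformed FASTA record at line 1 of ", path, ": expected '>'")
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) return(x)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- duplicated(ids)
  if (any(dup)) stop("duplicate sequence id in ", path, ": ", ids[dup][1L])
  names(x) <- ids
  S4Vectors::mcols(x)$description <- desc
  Biostrings::DNAStringSet(toupper(x))
}

#' Write sequences to FASTA
#'
#' @param x named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (length(x) > 0L && is.null(names(x)))
    stop("sequences must be named")
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc)) {
    keep <- !is.na(desc) & nzchar(desc)
    names(x)[keep] <- paste(names(x)[keep], desc[keep])
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write gene candidates to GFF3
#'
#' Each candidate becomes a `gene` feature carrying name, functionality,
#' family and strand, with its recombination signal (and, for single-exon
#' leaders, the leader interval) as child features. Coordinates are written
#' 1-based inclusive per the GFF3 specification.
#'
#' @param candidates a [GenomicRanges::GRanges] as returned by the scanners,
#'   optionally with `gene_name`, `call` and `family` metadata columns.
#' @param path output file.
#' @export
writeGff3 <- function(candidates, path) {
  stopifnot(methods::is(candidates, "GRanges"))
  if (length(candidates) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(candidates)
  getc <- function(col, default) {
    if (col %in% names(mc)) as.character(mc[[col]]) else
      rep(default, length(candidates))
  }
  ids <- getc("gene_name", NA_character_)
  ids[is.na(ids)] <- paste0(getc("gene_type", "segment")[is.na(ids)],
                            "_candidate_", which(is.na(ids)))
  genes <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(candidates),
    ranges = IRanges::ranges(candidates),
    strand = GenomicRanges::strand(candidates))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    source = "vdjkit", type = "gene", ID = ids, Name = ids,
    functionality = getc("call", NA_character_),
    gene_family = getc("family", NA_character_),
    leader_mode = getc("leader_mode", NA_character_))
  feats <- genes
  if (all(c("rss_start", "rss_end") %in% names(mc))) {
    has <- !is.na(mc$rss_start)
    if (any(has)) {
      rss <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(candidates)[has],
        ranges = IRanges::IRanges(mc$rss_start[has], mc$rss_end[has]),
        strand = GenomicRanges::strand(candidates)[has])
      S4Vectors::mcols(rss) <- S4Vectors::DataFrame(
        source = "vdjkit", type = "recombination_feature",
        ID = paste0(ids[has], ".rss"), Name = paste0(ids[has], ".rss"),
        functionality = NA_character_, gene_family = NA_character_,
        leader_mode = NA_character_)
      S4Vectors::mcols(rss)$Parent <- ids[has]
      S4Vectors::mcols(feats)$Parent <- NA_character_
      feats <- c(feats, rss)
    }
  }
  rtracklayer::export(feats, path, format = "gff3")
  invisible(path)
}
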