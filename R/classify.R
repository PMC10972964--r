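# Functionality classification (F / ORF / P) with machine-readable reason
# codes, for scanner candidates and for user-stated gene intervals.

P_REASONS <- c("stop_codon", "frameshift", "rss_no_cac")
ORF_REASONS <- c("missing_first_cys", "missing_trp",
                 "missing_second_cys_motif", "missing_fg", "rss_low_score",
                 "no_signal_peptide", "no_splice_donor", "no_splice_acceptor",
                 "missing_lpart1")

senseExtract <- function(s, start, end, strand) {
  if (strand == "-") revComp(substr(s, start, end)) else substr(s, start, end)
}

#' Evaluate a stated V gene interval for classification
#'
#' Unlike the scanner, which only emits candidates satisfying all criteria,
#' this computes every classifiable feature of a user-stated interval
#' (anchors, 3' RSS, leader signal, stop codons) so that defective genes can
#' be classified.
#'
#' @param seq a single named sequence (see [scanVGenes()]).
#' @param start,end 1-based inclusive interval on the forward strand, from
#'   gene start (ATG or spliced-exon start) to the base before the RSS `CAC`.
#' @param strand `"+"` or `"-"`.
#' @param leaderMode `"single_exon"` or `"spliced"`.
#' @param frame reading-frame offset of the V exon (0 for single-exon genes).
#' @param config a [vdjConfig()] list.
#' @return a candidate record (list) consumed by [classifyV()].
#' @export
evaluateVRegion <- function(seq, start, end, strand = "+",
                            leaderMode = c("spliced", "single_exon"),
                            frame = 0L, config = vdjConfig()) {
  leaderMode <- match.arg(leaderMode)
  s <- asNamedStrings(seq)[[1L]]
  n <- nchar(s)
  gene <- senseExtract(s, start, end, strand)
  flank <- if (strand == "+") substr(s, end + 1L, min(n, end + 40L))
           else revComp(substr(s, max(1L, start - 40L), start - 1L))
  upstream2 <- if (strand == "+") substr(s, start - 2L, start - 1L)
               else revComp(substr(s, end + 1L, min(n, end + 2L)))
  prot <- translateDNA(gene, frame)
  anch <- findConservedVAnchors(prot, config)
  rss <- rssOnFlank(flank, 23L, config)
  hasCac <- nchar(flank) >= 3L && substr(flank, 1L, 3L) == "CAC"
  sp <- if (!is.null(rss)) rss$spacer_len[1L] else 23L
  list(gene_type = "V", leader_mode = leaderMode, protein = prot,
       has_first_cys = "first_cys" %in% anch$name,
       has_trp = "conserved_trp" %in% anch$name,
       has_second_cys = "second_cys_motif" %in% anch$name,
       rss_cac = hasCac, rss_found = !is.null(rss),
       rss_heptamer = substr(flank, 1L, 7L),
       rss_spacer = substr(flank, 4L, 3L + sp),
       rss_nonamer = if (!is.null(rss)) rss$nonamer[1L] else
         substr(flank, 4L + sp, 12L + sp),
       leader_ok = if (leaderMode == "single_exon")
         substr(gene, 1L, 3L) == "ATG" else upstream2 == "AG",
       leader_protein = if (leaderMode == "single_exon")
         substr(prot, 1L, config$leaderAa) else NA_character_,
       frameshift = FALSE)
}

#' Evaluate a stated J gene interval for classification
#'
#' @inheritParams evaluateVRegion
#' @param coreOffset optional 1-based offset of the J core within the gene;
#'   used to anchor the reading frame when the core motif itself is mutated.
#' @return a candidate record (list) consumed by [classifyJ()].
#' @export
evaluateJRegion <- function(seq, start, end, strand = "+", coreOffset = NULL,
                            config = vdjConfig()) {
  s <- asNamedStrings(seq)[[1L]]
  n <- nchar(s)
  gene <- senseExtract(s, start, end, strand)
  donor6 <- if (strand == "+") substr(s, end + 1L, min(n, end + 6L))
            else revComp(substr(s, max(1L, start - 6L), start - 1L))
  flank <- if (strand == "+") revComp(substr(s, max(1L, start - 40L),
                                             start - 1L))
           else substr(s, end + 1L, min(n, end + 40L))
  cores <- scanIupac(J_CORE_PATTERN, gene)
  core <- if (length(cores) > 0L) cores[1L]
          else if (!is.null(coreOffset)) as.integer(coreOffset)
          else 1L
  frame <- (core - 1L) %% 3L
  prot <- translateDNA(gene, frame)
  coreAa <- (core - 1L - frame) %/% 3L + 1L
  fgOk <- length(cores) > 0L &&
    substr(prot, coreAa, coreAa + 1L) == "FG"
  rss <- rssOnFlank(flank, 12L, config)
  hasCac <- nchar(flank) >= 3L && substr(flank, 1L, 3L) == "CAC"
  list(gene_type = "J", protein = prot, has_core = length(cores) > 0L,
       fg_ok = fgOk,
       donor_ok = nchar(donor6) == 6L && matchIupac(SPLICE_DONOR_PATTERN,
                                                    donor6),
       rss_cac = hasCac, rss_found = !is.null(rss),
       rss_heptamer = substr(flank, 1L, 7L),
       rss_spacer = substr(flank, 4L,
                           3L + if (!is.null(rss)) rss$spacer_len[1L] else 12L),
       rss_nonamer = if (!is.null(rss)) rss$nonamer[1L] else "",
       frameshift = FALSE)
}

applyRssHook <- function(record, rssScoreHook, config) {
  if (is.null(rssScoreHook)) return(FALSE)
  if (is.null(config$rssScoreThreshold))
    stop("rssScoreHook supplied without rssScoreThreshold in config")
  score <- rssScoreHook(record$rss_heptamer, record$rss_spacer,
                        record$rss_nonamer)
  is.numeric(score) && score < config$rssScoreThreshold
}

finishCall <- function(reasons) {
  reasons <- unique(reasons)
  call <- if (any(reasons %in% P_REASONS)) "P"
          else if (length(reasons) > 0L) "ORF" else "F"
  list(call = call, reasons = reasons)
}

#' Classify a V candidate as F, ORF or P
#'
#' Functional (F) requires all three conserved anchors, a 3' 23-class RSS
#' beginning `CAC`, an intact leader signal and no stop codons. Stop codons,
#' frameshifts or a CAC-less RSS give a pseudogene (P); any other altered
#' feature gives ORF. Hooks default to a permissive pass so that
#' classification is reproducible offline: without hooks the
#' `no_signal_peptide` and `rss_low_score` codes never fire.
#'
#' @param candidate a record from [evaluateVRegion()] (or a scanner candidate
#'   converted with [as.list()] semantics).
#' @param signalPeptideHook optional `function(leaderProtein)` returning a
#'   list with element `pass` (and optionally `cleavage_offset`).
#' @param rssScoreHook optional `function(heptamer, spacer, nonamer)`
#'   returning a numeric score compared against `rssScoreThreshold`.
#' @param config a [vdjConfig()] list.
#' @return list with elements `call` (`"F"`, `"ORF"` or `"P"`) and `reasons`
#'   (character vector of reason codes, empty for F).
#' @export
classifyV <- function(candidate, signalPeptideHook = NULL,
                      rssScoreHook = NULL, config = vdjConfig()) {
  if (!identical(candidate$gene_type, "V"))
    stop("classifyV requires a V candidate")
  reasons <- character(0)
  if (grepl("*", candidate$protein, fixed = TRUE))
    reasons <- c(reasons, "stop_codon")
  if (isTRUE(candidate$frameshift)) reasons <- c(reasons, "frameshift")
  if (!isTRUE(candidate$rss_cac)) reasons <- c(reasons, "rss_no_cac")
  if (!isTRUE(candidate$has_first_cys))
    reasons <- c(reasons, "missing_first_cys")
  else if (!isTRUE(candidate$has_trp)) reasons <- c(reasons, "missing_trp")
  if (!isTRUE(candidate$has_second_cys))
    reasons <- c(reasons, "missing_second_cys_motif")
  if (!isTRUE(candidate$leader_ok))
    reasons <- c(reasons, if (identical(candidate$leader_mode, "spliced"))
      "no_splice_acceptor" else "missing_lpart1")
  if (!is.null(signalPeptideHook)) {
    res <- signalPeptideHook(candidate$leader_protein)
    if (!isTRUE(res$pass)) reasons <- c(reasons, "no_signal_peptide")
  }
  if (applyRssHook(candidate, rssScoreHook, config))
    reasons <- c(reasons, "rss_low_score")
  finishCall(reasons)
}

#' Classify a J candidate as F, ORF or P
#'
#' Functional requires the `FG` motif, a 5' 12-class RSS beginning `CAC`, a
#' 3' splice donor and no stop codons. A missing FG motif or donor demotes to
#' ORF; stop codons or a CAC-less RSS give a pseudogene.
#'
#' @inheritParams classifyV
#' @return list with `call` and `reasons`.
#' @export
classifyJ <- function(candidate, rssScoreHook = NULL, config = vdjConfig()) {
  if (!identical(candidate$gene_type, "J"))
    stop("classifyJ requires a J candidate")
  reasons <- character(0)
  if (grepl("*", candidate$protein, fixed = TRUE))
    reasons <- c(reasons, "stop_codon")
  if (isTRUE(candidate$frameshift)) reasons <- c(reasons, "frameshift")
  if (!isTRUE(candidate$rss_cac)) reasons <- c(reasons, "rss_no_cac")
  if (!isTRUE(candidate$fg_ok)) reasons <- c(reasons, "missing_fg")
  if (!isTRUE(candidate$donor_ok)) reasons <- c(reasons, "no_splice_donor")
  if (applyRssHook(candidate, rssScoreHook, config))
    reasons <- c(reasons, "rss_low_score")
  finishCall(reasons)
}

#' Classify every candidate in a scanner result
#'
#' @param candidates a [GenomicRanges::GRanges] from [scanVGenes()] /
#'   [scanJGenes()].
#' @param seq optionally, the scanned sequences (to extract RSS heptamer and
#'   spacer strings for `rssScoreHook`).
#' @inheritParams classifyV
#' @return a [S4Vectors::DataFrame] with columns `call` and `reasons`
#'   (CharacterList), parallel to `candidates`.
#' @export
classifyCandidates <- function(candidates, seq = NULL,
                               signalPeptideHook = NULL, rssScoreHook = NULL,
                               config = vdjConfig()) {
  stopifnot(methods::is(candidates, "GRanges"))
  mc <- S4Vectors::mcols(candidates)
  n <- length(candidates)
  calls <- character(n)
  reasons <- vector("list", n)
  seqs <- if (!is.null(seq)) asNamedStrings(seq) else NULL
  for (i in seq_len(n)) {
    type <- mc$gene_type[i]
    rec <- if (!is.null(seqs)) {
      nm <- as.character(GenomicRanges::seqnames(candidates)[i])
      if (type == "V")
        evaluateVRegion(seqs[nm], GenomicRanges::start(candidates)[i],
                        GenomicRanges::end(candidates)[i],
                        as.character(GenomicRanges::strand(candidates)[i]),
                        leaderMode = mc$leader_mode[i],
                        frame = mc$frame[i] %||% 0L, config = config)
      else
        evaluateJRegion(seqs[nm], GenomicRanges::start(candidates)[i],
                        GenomicRanges::end(candidates)[i],
                        as.character(GenomicRanges::strand(candidates)[i]),
                        config = config)
    } else if (type == "V") {
      list(gene_type = "V", leader_mode = mc$leader_mode[i],
           protein = mc$protein[i],
           has_first_cys = !is.na(mc$first_cys_aa[i]),
           has_trp = !is.na(mc$trp_aa[i]),
           has_second_cys = !is.na(mc$second_cys_aa[i]),
           rss_cac = !is.na(mc$rss_start[i]), rss_found = TRUE,
           rss_heptamer = NA_character_, rss_spacer = NA_character_,
           rss_nonamer = mc$rss_nonamer[i], leader_ok = TRUE,
           leader_protein = if (identical(mc$leader_mode[i], "single_exon"))
             substr(mc$protein[i], 1L, config$leaderAa) else NA_character_,
           frameshift = FALSE)
    } else {
      list(gene_type = "J", protein = mc$protein[i], has_core = TRUE,
           fg_ok = TRUE, donor_ok = !is.na(mc$donor_pos[i]),
           rss_cac = !is.na(mc$rss_start[i]), rss_found = TRUE,
           rss_heptamer = NA_character_, rss_spacer = NA_character_,
           rss_nonamer = mc$rss_nonamer[i], frameshift = FALSE)
    }
    res <- if (type == "V")
      classifyV(rec, signalPeptideHook, rssScoreHook, config)
    else classifyJ(rec, rssScoreHook, config)
    calls[i] <- res$call
    reasons[[i]] <- res$reasons
  }
  S4Vectors::DataFrame(call = calls,
                       reasons = IRanges::CharacterList(reasons))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Define the boundaries of a V gene
#'
#' The gene runs from the signal-peptide cleavage site (when an external
#' predictor supplies one) to the base before the RSS `CAC`. Without a
#' cleavage position the start falls back to the splice-acceptor-derived exon
#' start (spliced leaders) or the `ATG` (single-exon leaders) -- i.e. the
#' candidate's own start.
#'
#' @param candidate a 1-row [GenomicRanges::GRanges] V candidate.
#' @param cleavagePos optional forward-strand 1-based genomic coordinate of
#'   the first mature base.
#' @return a [GenomicRanges::GRanges] of length 1 with the gene boundaries.
#' @export
defineVBounds <- function(candidate, cleavagePos = NULL) {
  stopifnot(methods::is(candidate, "GRanges"), length(candidate) == 1L)
  mc <- S4Vectors::mcols(candidate)
  if (is.na(mc$rss_start))
    stop("candidate has no RSS; V bounds are undefined")
  out <- candidate
  if (!is.null(cleavagePos)) {
    if (as.character(GenomicRanges::strand(candidate)) == "-")
      GenomicRanges::end(out) <- as.integer(cleavagePos)
    else
      GenomicRanges::start(out) <- as.integer(cleavagePos)
  }
  out
}
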