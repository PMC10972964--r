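# V/J/D candidate scanners: slide over both strands of genomic DNA and emit
# candidates satisfying the combined anchor/RSS/open-reading-frame criteria.

#' Chicken V-gene family motifs
#'
#' Amino-acid motifs near the 5' end of the mature V protein used for
#' tentative family assignment.
#' @format named list of character vectors (family -> motifs).
#' @export
V_FAMILY_MOTIFS <- list(
  TRAV1 = "QVQQ", TRAV2 = "VSQQ", TRAV3 = "LQYP",
  TRBV1 = "LQQT", TRBV2 = "EINQ", TRBV3 = "ITQW",
  TRGV1 = "QVLLQQ", TRGV2 = "PIQS", TRGV3 = c("QAVPMQ", "QAAPVQ"),
  TRGV4 = "LWQSP",
  TRDV1 = "ETSGGGV", TRDV2 = "LEASGGG", TRDV3 = "VEFGGDV",
  TRDV4 = "RIVEAG", TRDV5 = "EIHAKKSA", TRDVH1 = "QIEMVTT")

#' Tentative V family from 5' amino-acid motifs
#'
#' The family whose motif begins within the first `familyK` residues of the
#' mature V protein (exact match). For single-exon candidates, whose protein
#' still carries the leader, the window is extended by the assumed leader
#' length (`leaderAa`). Ambiguous or absent motifs give `NA`.
#'
#' @param protein candidate V protein.
#' @param leaderMode `"spliced"`, `"single_exon"` or `"none"`.
#' @param config a [vdjConfig()] list.
#' @return family name or `NA_character_`.
#' @examples
#' assignFamily("QVQQLRSTC")
#' @export
assignFamily <- function(protein, leaderMode = "spliced",
                         config = vdjConfig()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  k <- config$familyK +
    if (identical(leaderMode, "single_exon")) config$leaderAa else 0L
  hits <- character(0)
  for (fam in names(V_FAMILY_MOTIFS)) {
    for (m in V_FAMILY_MOTIFS[[fam]]) {
      p <- regexpr(m, protein, fixed = TRUE)
      if (p > 0L && p <= k) { hits <- c(hits, fam); break }
    }
  }
  if (length(hits) == 1L) hits else NA_character_
}

asNamedStrings <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    out <- as.character(seq)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(toupper(out))
  }
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  stopifnot(is.character(seq))
  if (is.null(names(seq))) names(seq) <- paste0("seq", seq_along(seq))
  toupper(seq)
}

emptyCandidates <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_type = character(0), leader_mode = character(0),
    splice_acceptor_pos = integer(0), frame = integer(0),
    protein = character(0), family = character(0),
    first_cys_aa = integer(0), trp_aa = integer(0),
    second_cys_aa = integer(0), second_cys_text = character(0),
    core_pos = integer(0), donor_pos = integer(0),
    rss_spacer_class = integer(0), rss_spacer_len = integer(0),
    rss_nonamer = character(0), rss_start = integer(0), rss_end = integer(0),
    rss5_spacer_len = integer(0), rss3_spacer_len = integer(0),
    notes = character(0))
  gr
}

candidateRow <- function(...) {
  defaults <- list(start = NA_integer_, end = NA_integer_,
                   gene_type = NA_character_, leader_mode = NA_character_,
                   splice_acceptor_pos = NA_integer_, frame = NA_integer_,
                   protein = NA_character_, family = NA_character_,
                   first_cys_aa = NA_integer_, trp_aa = NA_integer_,
                   second_cys_aa = NA_integer_,
                   second_cys_text = NA_character_,
                   core_pos = NA_integer_, donor_pos = NA_integer_,
                   rss_spacer_class = NA_integer_,
                   rss_spacer_len = NA_integer_, rss_nonamer = NA_character_,
                   rss_start = NA_integer_, rss_end = NA_integer_,
                   rss5_spacer_len = NA_integer_,
                   rss3_spacer_len = NA_integer_, notes = "")
  args <- list(...)
  defaults[names(args)] <- args
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

# Mirror strand-local candidate coordinates (relative to the reverse
# complement) back onto the forward strand of a sequence of length n.
mirrorRows <- function(df, n) {
  if (nrow(df) == 0L) return(df)
  flip2 <- function(a, b) list(n - b + 1L, n - a + 1L)
  se <- flip2(df$start, df$end)
  df$start <- se[[1]]; df$end <- se[[2]]
  rs <- flip2(df$rss_start, df$rss_end)
  df$rss_start <- rs[[1]]; df$rss_end <- rs[[2]]
  df$splice_acceptor_pos <- ifelse(
    is.na(df$splice_acceptor_pos), NA_integer_,
    n - (df$splice_acceptor_pos + 1L) + 1L)
  df$core_pos <- ifelse(is.na(df$core_pos), NA_integer_,
                        n - (df$core_pos + 10L) + 1L)
  df$donor_pos <- ifelse(is.na(df$donor_pos), NA_integer_,
                         n - (df$donor_pos + 5L) + 1L)
  df
}

rowsToGRanges <- function(rows, seqName) {
  if (length(rows) == 0L) return(emptyCandidates())
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = seqName,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  keep <- setdiff(names(df), c("start", "end", "strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[keep])
  gr
}

sortCandidates <- function(gr) {
  if (length(gr) == 0L) return(gr)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr),
             as.character(GenomicRanges::strand(gr)))
  gr[o]
}

# V candidates on one strand of one sequence; coordinates relative to `s`.
scanVOneStrand <- function(s, config) {
  n <- nchar(s)
  out <- list()
  minLen <- config$vExonLen[1]; maxLen <- config$vExonLen[2]
  for (cac in scanIupac("CAC", s)) {
    rss <- findRss(s, cac - 1L, "downstream_of_v", config)
    if (nrow(rss) == 0L) next
    rss <- rss[1L, ]
    exonEnd <- cac - 1L
    if (exonEnd < minLen) next
    startMin <- max(1L, exonEnd - maxLen + 1L)
    startMax <- exonEnd - minLen + 1L
    anchorCands <- list()
    addCand <- function(start, mode, acceptor, frame, prot, anch) {
      getPos <- function(nm) {
        i <- match(nm, anch$name)
        if (is.na(i)) NA_integer_ else anch$pos[i]
      }
      anchorCands[[length(anchorCands) + 1L]] <<- candidateRow(
        start = start, end = exonEnd, gene_type = "V", leader_mode = mode,
        splice_acceptor_pos = acceptor, frame = frame, protein = prot,
        first_cys_aa = getPos("first_cys"), trp_aa = getPos("conserved_trp"),
        second_cys_aa = getPos("second_cys_motif"),
        second_cys_text = anch$matched_text[match("second_cys_motif",
                                                  anch$name)],
        rss_spacer_class = 23L, rss_spacer_len = rss$spacer_len,
        rss_nonamer = rss$nonamer, rss_start = rss$rss_start,
        rss_end = rss$rss_end)
    }
    for (m in startMin:startMax) {
      if (substr(s, m, m + 2L) != "ATG") next
      prot <- translateDNA(substr(s, m, exonEnd))
      if (grepl("*", prot, fixed = TRUE)) next
      anch <- findConservedVAnchors(prot, config)
      if (all(c("first_cys", "conserved_trp", "second_cys_motif") %in%
              anch$name))
        addCand(m, "single_exon", NA_integer_, 0L, prot, anch)
    }
    for (p in (startMin - 2L):(startMax - 2L)) {
      if (p < 1L || substr(s, p, p + 1L) != "AG") next
      exonStart <- p + 2L
      for (f in 0:2) {
        prot <- translateDNA(substr(s, exonStart, exonEnd), frame = f)
        if (grepl("*", prot, fixed = TRUE)) next
        anch <- findConservedVAnchors(prot, config)
        if (all(c("first_cys", "conserved_trp", "second_cys_motif") %in%
                anch$name)) {
          addCand(exonStart, "spliced", p, f, prot, anch)
          break
        }
      }
    }
    if (length(anchorCands) == 0L) next
    # same 3' RSS: keep the candidate with the longest open leader/frame
    df <- do.call(rbind, anchorCands)
    df <- df[order(df$start, df$leader_mode), , drop = FALSE]
    out[[length(out) + 1L]] <- df[1L, , drop = FALSE]
  }
  if (length(out) == 0L) return(candidateRow()[0L, ])
  do.call(rbind, out)
}

#' Scan genomic DNA for V gene candidates
#'
#' Slides over both strands and emits candidates where either an in-frame
#' `ATG` (single-exon leader) or an `AG` splice acceptor (spliced leader)
#' opens a reading frame without stop codons that carries all three conserved
#' V anchors and ends at a 3' 23-class CAC RSS. The candidate interval ends at
#' the base before the RSS `CAC`. Candidates sharing the same 3' RSS on one
#' strand are collapsed to the one with the longest open leader; reverse-
#' strand candidates are reported with strand `-` in forward coordinates.
#'
#' @param seq a named [Biostrings::DNAStringSet], `DNAString` or named
#'   character vector of genomic sequences.
#' @param config a [vdjConfig()] list.
#' @return a [GenomicRanges::GRanges] of candidates, sorted by sequence,
#'   start and strand, with motif/RSS/protein metadata columns.
#' @export
scanVGenes <- function(seq, config = vdjConfig()) {
  seqs <- asNamedStrings(seq)
  pieces <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    fwd <- scanVOneStrand(s, config)
    fwd$strand <- rep("+", nrow(fwd))
    rev <- mirrorRows(scanVOneStrand(revComp(s), config), nchar(s))
    rev$strand <- rep("-", nrow(rev))
    both <- rbind(fwd, rev)
    if (nrow(both) == 0L) next
    both$family <- vapply(seq_len(nrow(both)), function(i)
      assignFamily(both$protein[i], both$leader_mode[i], config),
      character(1L))
    pieces[[nm]] <- rowsToGRanges(split(both, seq_len(nrow(both))), nm)
  }
  if (length(pieces) == 0L) return(emptyCandidates())
  sortCandidates(do.call(c, unname(pieces)))
}

scanJOneStrand <- function(s, config) {
  n <- nchar(s)
  out <- list()
  jMin <- config$jLen[1]; jMax <- config$jLen[2]
  for (q in scanIupac(J_CORE_PATTERN, s)) {
    for (g in seq.int(max(4L, q - jMax + 1L), q)) {
      if (substr(s, g - 3L, g - 1L) != "GTG") next
      rss <- findRss(s, g, "upstream_of_j", config)
      if (nrow(rss) == 0L) next
      rss <- rss[1L, ]
      dRegionEnd <- min(n, g + jMax)
      if (q + 11L > dRegionEnd) next
      dRel <- scanIupac(SPLICE_DONOR_PATTERN, substr(s, q + 11L, dRegionEnd))
      for (d in dRel + q + 10L) {
        len <- d - g
        if (len < jMin || len > jMax) next
        body <- substr(s, q, d - 1L)
        prot <- translateDNA(body)
        if (grepl("*", prot, fixed = TRUE) || substr(prot, 1L, 2L) != "FG")
          next
        hasSecondary <- length(scanIupac(J_SECONDARY_PATTERN, body)) > 0L
        if (!hasSecondary && !config$relaxJSecondary) next
        out[[length(out) + 1L]] <- candidateRow(
          start = g, end = d - 1L, gene_type = "J", leader_mode = "none",
          frame = 0L, protein = prot, core_pos = q, donor_pos = d,
          rss_spacer_class = 12L, rss_spacer_len = rss$spacer_len,
          rss_nonamer = rss$nonamer, rss_start = rss$rss_start,
          rss_end = rss$rss_end,
          notes = if (hasSecondary) "" else "j_secondary_missing")
        break
      }
      if (length(out) > 0L && out[[length(out)]]$start == g) break
    }
  }
  if (length(out) == 0L) return(candidateRow()[0L, ])
  df <- do.call(rbind, out)
  df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
}

#' Scan genomic DNA for J gene candidates
#'
#' Emits candidates spanning from the base after the 5' 12-class RSS heptamer
#' to the base before the `GTRDGD` splice donor, requiring the J core
#' `TTYGGNNNNGG` translating `FG`, no stop codon in the J reading frame, the
#' confirmatory `TNNBNRT` motif between core and donor (unless
#' `relaxJSecondary`), and a length inside the configured window. Both
#' strands are scanned.
#'
#' @inheritParams scanVGenes
#' @return a [GenomicRanges::GRanges] of J candidates.
#' @export
scanJGenes <- function(seq, config = vdjConfig()) {
  seqs <- asNamedStrings(seq)
  pieces <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    fwd <- scanJOneStrand(s, config)
    fwd$strand <- rep("+", nrow(fwd))
    rev <- mirrorRows(scanJOneStrand(revComp(s), config), nchar(s))
    rev$strand <- rep("-", nrow(rev))
    both <- rbind(fwd, rev)
    if (nrow(both) == 0L) next
    pieces[[nm]] <- rowsToGRanges(split(both, seq_len(nrow(both))), nm)
  }
  if (length(pieces) == 0L) return(emptyCandidates())
  sortCandidates(do.call(c, unname(pieces)))
}

scanDOneStrand <- function(s, lo, hi, config) {
  out <- list()
  dMin <- config$dLen[1]; dMax <- config$dLen[2]
  starts <- integer(0)
  for (t in seq.int(max(4L, lo), hi)) {
    if (substr(s, t - 3L, t - 1L) != "GTG") next
    if (nrow(findRss(s, t, "upstream_of_j", config)) > 0L)
      starts <- c(starts, t)
  }
  for (t in starts) {
    for (cac in scanIupac("CAC", substr(s, t + dMin, min(hi + 1L, t + dMax))) +
           t + dMin - 1L) {
      rss3 <- findRss(s, cac - 1L, "downstream_of_v", config)
      if (nrow(rss3) == 0L) next
      segment <- substr(s, t, cac - 1L)
      open <- vapply(0:2, function(f)
        !grepl("*", translateDNA(segment, f), fixed = TRUE), logical(1L))
      if (!any(open)) next
      rss5 <- findRss(s, t, "upstream_of_j", config)
      out[[length(out) + 1L]] <- candidateRow(
        start = t, end = cac - 1L, gene_type = "D", leader_mode = "none",
        rss_start = rss5$rss_start[1L], rss_end = rss3$rss_end[1L],
        rss5_spacer_len = rss5$spacer_len[1L],
        rss3_spacer_len = rss3$spacer_len[1L],
        notes = paste0("frames_open=",
                       paste(which(open) - 1L, collapse = ",")))
    }
  }
  if (length(out) == 0L) return(candidateRow()[0L, ])
  df <- do.call(rbind, out)
  df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
}

#' Scan a user-supplied window for D segments
#'
#' D segments are short sequences flanked by a 5' 12-class RSS and a 3'
#' 23-class RSS with at least one open reading frame (per-frame openness is
#' recorded in `notes`). Because the pattern has low specificity, an explicit
#' window is required; genome-wide blind scans are refused.
#'
#' @param seq a single named sequence (as in [scanVGenes()]).
#' @param window integer `c(start, end)` (1-based) or a
#'   [GenomicRanges::GRanges] of length 1 delimiting the search region.
#' @param config a [vdjConfig()] list.
#' @return a [GenomicRanges::GRanges] of D candidates.
#' @export
scanDSegments <- function(seq, window, config = vdjConfig()) {
  seqs <- asNamedStrings(seq)
  if (length(seqs) != 1L) stop("scanDSegments expects a single sequence")
  if (missing(window) || is.null(window))
    stop("D-segment scanning requires an explicit window")
  if (methods::is(window, "GRanges")) {
    stopifnot(length(window) == 1L)
    window <- c(GenomicRanges::start(window), GenomicRanges::end(window))
  }
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  s <- seqs[[1L]]
  n <- nchar(s)
  lo <- max(1L, window[1]); hi <- min(n, window[2])
  fwd <- scanDOneStrand(s, lo, hi, config)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- mirrorRows(scanDOneStrand(revComp(s), n - hi + 1L, n - lo + 1L,
                                   config), n)
  rev$strand <- rep("-", nrow(rev))
  both <- rbind(fwd, rev)
  if (nrow(both) == 0L) return(emptyCandidates())
  sortCandidates(rowsToGRanges(split(both, seq_len(nrow(both))),
                               names(seqs)))
}
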