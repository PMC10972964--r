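# Anchor motifs: CAC-anchored recombination signal sequences (RSS) with
# 12/23 (+/-1) spacers, the conserved V-domain amino-acid anchors, and the
# J-segment nucleotide motifs.

SECOND_CYS_MOTIFS <- c("YYC", "YFC", "YLC", "YHC", "YIC", "TFC")
J_CORE_PATTERN <- "TTYGGNNNNGG"
J_SECONDARY_PATTERN <- "TNNBNRT"
SPLICE_DONOR_PATTERN <- "GTRDGD"

# mismatch count of a plain-ACGT window against an IUPAC pattern
# (non-ACGT window characters always count as mismatches)
iupacMismatches <- function(pattern, window) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  sum(!vapply(seq_along(p), function(i) {
    w[i] %in% c("A", "C", "G", "T") && w[i] %in% IUPAC_SETS[[p[i]]]
  }, logical(1L)))
}

emptyRssHits <- function() {
  data.frame(cac_pos = integer(0), spacer_class = integer(0),
             spacer_len = integer(0), side = character(0),
             nonamer = character(0), nonamer_mismatches = integer(0),
             rss_start = integer(0), rss_end = integer(0),
             stringsAsFactors = FALSE)
}

# Core RSS test on a flank read away from the gene body, starting at the
# expected "CAC". Layout: CAC anchor, then `spacer_len` nucleotides, then the
# 9-nt nonamer. The spacer length is pinned by locating the nonamer consensus
# (config) at offsets {class-1, class, class+1}; full heptamer/nonamer
# probabilistic scoring is delegated to an external hook.
rssOnFlank <- function(flank, spacerClass, config) {
  if (nchar(flank) < 3L || substr(flank, 1L, 3L) != "CAC") return(NULL)
  rows <- list()
  for (sp in spacerClass + (-1L:1L)) {
    nstart <- 3L + sp + 1L
    nonamer <- substr(flank, nstart, nstart + 8L)
    if (nchar(nonamer) < 9L) next
    mm <- iupacMismatches(config$nonamer, nonamer)
    if (mm <= config$nonamerMaxMismatch) {
      rows[[length(rows) + 1L]] <- data.frame(
        spacer_len = sp, nonamer = nonamer, nonamer_mismatches = mm,
        flank_end = nstart + 8L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$nonamer_mismatches, abs(out$spacer_len - spacerClass)), ,
      drop = FALSE]
}

#' Locate a recombination signal sequence at a gene boundary
#'
#' The heptamer must literally begin `CAC` on the gene's sense strand reading
#' away from the gene body: downstream of a V gene (23-class spacer) or
#' upstream of a J gene (12-class spacer). The spacer length is accepted at
#' the canonical class +/- 1 and is pinned by locating the nonamer consensus;
#' the nonamer is recorded but not probabilistically scored (see
#' `rssScoreHook` in [classifyV()]).
#'
#' @param seq sense-strand DNA string containing the gene and its flank.
#' @param anchorPos the gene boundary (1-based): last base of the V gene for
#'   `"downstream_of_v"`, first base of the J gene for `"upstream_of_j"`.
#' @param orientation `"downstream_of_v"` (23-class) or `"upstream_of_j"`
#'   (12-class).
#' @param config a [vdjConfig()] list.
#' @return data.frame of hits (possibly empty) with the CAC position, spacer
#'   class and length, side, nonamer and its mismatch count, and the RSS span
#'   on `seq` (1-based inclusive).
#' @export
findRss <- function(seq, anchorPos,
                    orientation = c("downstream_of_v", "upstream_of_j"),
                    config = vdjConfig()) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  anchorPos <- as.integer(anchorPos)
  if (orientation == "downstream_of_v") {
    if (anchorPos < 0L || anchorPos >= n) return(emptyRssHits())
    flank <- substr(seq, anchorPos + 1L, min(n, anchorPos + 40L))
    hits <- rssOnFlank(flank, 23L, config)
    if (is.null(hits)) return(emptyRssHits())
    data.frame(cac_pos = anchorPos + 1L, spacer_class = 23L,
               spacer_len = hits$spacer_len, side = "three_prime",
               nonamer = hits$nonamer,
               nonamer_mismatches = hits$nonamer_mismatches,
               rss_start = anchorPos + 1L,
               rss_end = anchorPos + hits$flank_end,
               stringsAsFactors = FALSE)
  } else {
    if (anchorPos <= 1L || anchorPos > n + 1L) return(emptyRssHits())
    lo <- max(1L, anchorPos - 40L)
    flank <- revComp(substr(seq, lo, anchorPos - 1L))
    hits <- rssOnFlank(flank, 12L, config)
    if (is.null(hits)) return(emptyRssHits())
    data.frame(cac_pos = anchorPos - 1L, spacer_class = 12L,
               spacer_len = hits$spacer_len, side = "five_prime",
               nonamer = hits$nonamer,
               nonamer_mismatches = hits$nonamer_mismatches,
               rss_start = anchorPos - hits$flank_end,
               rss_end = anchorPos - 1L,
               stringsAsFactors = FALSE)
  }
}

emptyMotifHits <- function() {
  data.frame(name = character(0), pos = integer(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

#' Locate the conserved V-domain amino-acid anchors
#'
#' Reports the 1st-CYS (first `C` inside its window), the CONSERVED-TRP (first
#' `W` within the configured spacing after the 1st-CYS) and the rightmost
#' 2nd-CYS motif (one of `YYC/YFC/YLC/YHC/YIC/TFC`) starting inside its
#' window. A V candidate passes the anchor test iff all three are present.
#'
#' @param protein translated V-exon amino-acid string.
#' @param config a [vdjConfig()] list (anchor windows, in aa).
#' @return data.frame with columns `name`, `pos` (1-based aa position) and
#'   `matched_text`; rows only for anchors that were found.
#' @export
findConservedVAnchors <- function(protein, config = vdjConfig()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  hits <- emptyMotifHits()
  w <- config$firstCysWindowAa
  idx <- seq.int(min(w[1], n), min(w[2], n))
  cys <- if (w[1] > n) integer(0) else idx[aa[idx] == "C"]
  if (length(cys) > 0L) {
    cys <- cys[1L]
    hits <- rbind(hits, data.frame(name = "first_cys", pos = cys,
                                   matched_text = "C"))
    tw <- config$trpOffsetAa
    tidx <- seq.int(min(cys + tw[1], n + 1L), min(cys + tw[2], n))
    trp <- tidx[tidx <= n & aa[tidx] == "W"]
    if (length(trp) > 0L)
      hits <- rbind(hits, data.frame(name = "conserved_trp", pos = trp[1L],
                                     matched_text = "W"))
  }
  sw <- config$secondCysWindowAa
  if (n < sw[1]) return(hits)
  best <- NULL
  for (s in seq.int(min(sw[1], n), min(sw[2], n - 2L))) {
    if (s < 1L || s + 2L > n) next
    tri <- paste(aa[s:(s + 2L)], collapse = "")
    if (tri %in% SECOND_CYS_MOTIFS) best <- c(s, tri)
  }
  if (!is.null(best))
    hits <- rbind(hits, data.frame(name = "second_cys_motif",
                                   pos = as.integer(best[1L]),
                                   matched_text = best[2L]))
  hits
}

#' Locate J-segment nucleotide motifs
#'
#' Scans a candidate J region (sense strand) for the J core `TTYGGNNNNGG`
#' (whose frame must translate with `FG` as its first two codons), the
#' confirmatory `TNNBNRT` motif and the splice donor `GTRDGD`.
#'
#' @param seq DNA string of the candidate J region on its sense strand.
#' @param config a [vdjConfig()] list.
#' @return data.frame with columns `name` (`j_core`, `fg_motif`,
#'   `j_secondary`, `splice_donor`), `pos` and `matched_text`.
#' @export
findJAnchors <- function(seq, config = vdjConfig()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  rows <- list()
  for (q in scanIupac(J_CORE_PATTERN, seq)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "j_core", pos = q,
      matched_text = substr(seq, q, q + 10L), stringsAsFactors = FALSE)
    fg <- substr(translateDNA(substr(seq, q, nchar(seq))), 1L, 2L)
    if (identical(fg, "FG"))
      rows[[length(rows) + 1L]] <- data.frame(
        name = "fg_motif", pos = q, matched_text = "FG",
        stringsAsFactors = FALSE)
  }
  for (p in scanIupac(J_SECONDARY_PATTERN, seq))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "j_secondary", pos = p,
      matched_text = substr(seq, p, p + 6L), stringsAsFactors = FALSE)
  for (d in scanIupac(SPLICE_DONOR_PATTERN, seq))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "splice_donor", pos = d,
      matched_text = substr(seq, d, d + 5L), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(emptyMotifHits())
  do.call(rbind, rows)
}
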