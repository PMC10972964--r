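# Post-clonotyping repertoire summary statistics from AIRR-style clonotype
# tables (sample_id, chain, v_call, j_call, cdr3, cdr3_aa, umi_count).

CLONOTYPE_COLS <- c("sample_id", "chain", "v_call", "j_call", "cdr3",
                    "cdr3_aa", "umi_count")

#' Read an AIRR-style clonotype table
#'
#' Tab-separated with a header row; required columns: `sample_id`, `chain`,
#' `v_call`, `j_call`, `cdr3` (nucleotide), `cdr3_aa`, `umi_count`.
#'
#' @param path TSV file path.
#' @return data.frame of clonotypes.
#' @export
readClonotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateClonotypes(df)
}

validateClonotypes <- function(df) {
  missing <- setdiff(CLONOTYPE_COLS, names(df))
  if (length(missing) > 0L)
    stop("clonotype table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) > 0L && any(df$umi_count < 1L))
    stop("umi_count must be >= 1")
  df
}

#' Drop non-expressed clonotypes
#'
#' Clonotypes whose CDR3 amino-acid sequence contains a stop codon, or whose
#' nucleotide CDR3 is not translatable (length not a multiple of three), are
#' excluded; the number removed is attached as attribute `n_excluded`.
#'
#' @param df clonotype data.frame.
#' @return filtered data.frame with attribute `n_excluded`.
#' @export
filterProductive <- function(df) {
  validateClonotypes(df)
  bad <- grepl("*", df$cdr3_aa, fixed = TRUE) | nchar(df$cdr3) %% 3L != 0L
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Downsample clonotype tables to the smallest sample
#'
#' Within each chain, every sample is randomly downsampled at the UMI level
#' (without replacement) to the total UMI count of the smallest sample, so
#' that per-sample statistics are comparable. Seeded and reproducible.
#'
#' @param df clonotype data.frame (all samples stacked).
#' @param seed integer seed.
#' @return downsampled data.frame.
#' @export
downsampleClonotypes <- function(df, seed = 1L) {
  validateClonotypes(df)
  if (nrow(df) == 0L) stop("empty clonotype table")
  withSeed(seed, {
    out <- list()
    for (ch in unique(df$chain)) {
      sub <- df[df$chain == ch, , drop = FALSE]
      totals <- tapply(sub$umi_count, sub$sample_id, sum)
      if (any(totals == 0L)) stop("sample with zero UMIs in chain ", ch)
      M <- min(totals)
      for (sid in unique(sub$sample_id)) {
        tab <- sub[sub$sample_id == sid, , drop = FALSE]
        umis <- rep(seq_len(nrow(tab)), tab$umi_count)
        keep <- if (length(umis) > M) sample(umis, M) else umis
        counts <- tabulate(keep, nbins = nrow(tab))
        tab$umi_count <- counts
        out[[paste(ch, sid)]] <- tab[counts > 0L, , drop = FALSE]
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

normalizeCalls <- function(x) {
  x[is.na(x) | !nzchar(x)] <- "other"
  x
}

#' UMI-weighted V/J usage and V-J pairing frequencies
#'
#' @param df clonotype data.frame (one chain).
#' @return list with `v_usage` and `j_usage` (named numerics summing to 1)
#'   and `vj` (data.frame `v_call`, `j_call`, `freq`).
#' @export
usageAndPairing <- function(df) {
  validateClonotypes(df)
  if (nrow(df) == 0L) stop("empty clonotype table")
  w <- df$umi_count / sum(df$umi_count)
  v <- normalizeCalls(df$v_call)
  j <- normalizeCalls(df$j_call)
  vU <- tapply(w, v, sum)
  jU <- tapply(w, j, sum)
  vj <- stats::aggregate(list(freq = w),
                         by = list(v_call = v, j_call = j), FUN = sum)
  list(v_usage = c(vU[order(names(vU))]), j_usage = c(jU[order(names(jU))]),
       vj = vj[order(vj$v_call, vj$j_call), , drop = FALSE])
}

#' @rdname spectratype
#' @export
setMethod("spectratype", "data.frame", function(x, ...) {
  validateClonotypes(x)
  if (nrow(x) == 0L) stop("empty clonotype table")
  w <- x$umi_count / sum(x$umi_count)
  out <- tapply(w, nchar(x$cdr3_aa), sum)
  c(out[order(as.integer(names(out)))])
})

clonotypeKey <- function(df, key = c("aa", "nt")) {
  key <- match.arg(key)
  if (key == "aa") paste(df$v_call, df$j_call, df$cdr3_aa, sep = "|")
  else paste(df$v_call, df$j_call, df$cdr3, sep = "|")
}

#' Publicity of clonotypes across samples
#'
#' A clonotype (keyed by V call, J call and CDR3 amino-acid sequence by
#' default, or nucleotide sequence) found in all samples is "public"; one
#' found in a single sample is "private". Reports, per sample, the
#' UMI-weighted share of the repertoire occupied by clonotypes found in k
#' samples, for each k.
#'
#' @param df clonotype data.frame with at least two samples.
#' @param key `"aa"` or `"nt"` clonotype identity.
#' @return list with `classification` (data.frame key -> `n_samples`),
#'   `shares` (matrix sample x k, rows summing to 1) and `mean_share`
#'   (named numeric over k).
#' @export
publicity <- function(df, key = c("aa", "nt")) {
  validateClonotypes(df)
  samples <- unique(df$sample_id)
  if (length(samples) < 2L) stop("publicity requires at least two samples")
  k <- clonotypeKey(df, key)
  presence <- tapply(df$sample_id, k, function(s) length(unique(s)))
  S <- length(samples)
  shares <- matrix(0, nrow = S, ncol = S,
                   dimnames = list(samples, as.character(seq_len(S))))
  for (sid in samples) {
    sub <- df$sample_id == sid
    w <- df$umi_count[sub] / sum(df$umi_count[sub])
    ks <- presence[k[sub]]
    agg <- tapply(w, ks, sum)
    shares[sid, names(agg)] <- agg
  }
  list(classification = data.frame(key = names(presence),
                                   n_samples = as.integer(presence),
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
       shares = shares,
       mean_share = colMeans(shares))
}

#' CDR3 amino-acid convergence
#'
#' Number of distinct nucleotide sequences encoding each CDR3 amino-acid
#' sequence.
#'
#' @param df clonotype data.frame.
#' @return named integer vector, CDR3 aa -> count of distinct CDR3 nt.
#' @export
convergence <- function(df) {
  validateClonotypes(df)
  out <- tapply(df$cdr3, df$cdr3_aa, function(x) length(unique(x)))
  vapply(out, as.integer, integer(1L))
}

#' Repertoire share by clonotype abundance rank group
#'
#' Clonotypes are ranked by UMI-weighted abundance and grouped at the given
#' rank boundaries; each group's share of the repertoire is returned.
#'
#' @param df clonotype data.frame.
#' @param boundaries increasing upper rank bounds (default decades
#'   `c(10, 100, 1000)`; ranks beyond the last bound form the final group).
#' @return named numeric of group shares summing to 1.
#' @export
rankAbundance <- function(df, boundaries = c(10L, 100L, 1000L)) {
  validateClonotypes(df)
  if (nrow(df) == 0L) stop("empty clonotype table")
  stopifnot(all(diff(boundaries) > 0L))
  w <- df$umi_count / sum(df$umi_count)
  ord <- order(-w, clonotypeKey(df))
  w <- w[ord]
  lo <- c(1L, boundaries + 1L)
  hi <- c(boundaries, length(w))
  labels <- ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi))
  labels[length(labels)] <- paste0(lo[length(lo)], "+")
  out <- vapply(seq_along(lo), function(i) {
    if (lo[i] > length(w)) 0 else sum(w[lo[i]:min(hi[i], length(w))])
  }, numeric(1L))
  stats::setNames(out, labels)
}

#' Mean amino-acid counts per CDR3
#'
#' Frequency-weighted mean count of each amino acid per CDR3.
#'
#' @param df clonotype data.frame.
#' @return named numeric over the 20 amino acids.
#' @export
aaComposition <- function(df) {
  validateClonotypes(df)
  if (nrow(df) == 0L) stop("empty clonotype table")
  w <- df$umi_count / sum(df$umi_count)
  out <- vapply(AA20, function(a) {
    counts <- nchar(df$cdr3_aa) -
      nchar(gsub(a, "", df$cdr3_aa, fixed = TRUE))
    sum(w * counts)
  }, numeric(1L))
  out
}

#' Flag chimeric receptors
#'
#' A clonotype is chimeric when its V call belongs to a different chain's
#' locus than the table's chain (e.g. a TRAV gene recombined into a delta
#' chain rearrangement).
#'
#' @param df clonotype data.frame.
#' @param chain expected chain; defaults to the table's (unique) `chain`.
#' @return logical vector flagging chimeric rows.
#' @export
flagChimeras <- function(df, chain = NULL) {
  validateClonotypes(df)
  if (is.null(chain)) {
    chain <- unique(df$chain)
    if (length(chain) != 1L)
      stop("table contains multiple chains; pass `chain` explicitly")
  }
  vChain <- substr(sub("^(orf|p)", "", normalizeCalls(df$v_call)), 1L, 3L)
  vChain != chain & vChain %in% c("TRA", "TRB", "TRG", "TRD")
}
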