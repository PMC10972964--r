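# Independent oracles and small fixture builders used across tests.

randDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# is the character vector x a subsequence of y?
isSubseqOf <- function(x, y) {
  i <- 1L
  for (ch in y) if (i <= length(x) && ch == x[i]) i <- i + 1L
  i > length(x)
}

# true brute force: enumerate every subsequence of the shorter string
bruteLcsExhaustive <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(av) > length(bv)) { tmp <- av; av <- bv; bv <- tmp }
  n <- length(av)
  best <- 0L
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in 0:(2^n - 1L)) {
    sel <- av[bitwAnd(mask, bits) > 0L]
    if (length(sel) > best && isSubseqOf(sel, bv)) best <- length(sel)
  }
  best
}

# independent plain-R implementation of the LCS recurrence
lcsRecurrence <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (av[i] == bv[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

# brute-force IUPAC matcher by full set expansion of the pattern
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupacExpand <- function(pattern) {
  sets <- IUPAC_ORACLE[strsplit(pattern, "", fixed = TRUE)[[1L]]]
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1L,
        paste, collapse = "")
}

# a constructed RSS flank: CAC + spacer + nonamer + pad
makeFlank <- function(spacerLen, nonamer = "ACAAAAACC") {
  paste0("CAC", strrep("TG", ceiling(spacerLen / 2)) |>
           substr(1L, spacerLen), nonamer, "GGGG")
}

truthGRanges <- function(truth, type) {
  tr <- truth[truth$gene_type == type, , drop = FALSE]
  GenomicRanges::GRanges(tr$seq_id,
                         IRanges::IRanges(tr$start, tr$end), tr$strand)
}

expectExactRecovery <- function(found, truth, type) {
  tr <- truth[truth$gene_type == type & truth$defect == "none", ,
              drop = FALSE]
  expect_equal(length(found), nrow(tr))
  expect_equal(GenomicRanges::start(found), tr$start)
  expect_equal(GenomicRanges::end(found), tr$end)
  expect_equal(as.character(GenomicRanges::strand(found)), tr$strand)
}

totalVariation <- function(p, q) {
  nm <- union(names(p), names(q))
  pv <- stats::setNames(rep(0, length(nm)), nm); pv[names(p)] <- p
  qv <- stats::setNames(rep(0, length(nm)), nm); qv[names(q)] <- q
  sum(abs(pv - qv)) / 2
}

# two-template family fixture: returns named gene vector + template labels
mutateSeq <- function(s, k) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- sample(length(v), k)
  v[idx] <- vapply(v[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  paste(v, collapse = "")
}

twoTemplateGenes <- function(seed, n = 3L, len = 300L, mutFrac = 0.1) {
  set.seed(seed)
  t1 <- randDna(len)
  t2 <- randDna(len)
  k <- round(mutFrac * len)
  genes <- c(
    stats::setNames(vapply(seq_len(n), function(i) mutateSeq(t1, k),
                           character(1L)), paste0("a", seq_len(n))),
    stats::setNames(vapply(seq_len(n), function(i) mutateSeq(t2, k),
                           character(1L)), paste0("b", seq_len(n))))
  list(genes = genes,
       labels = rep(c("a", "b"), each = n), t1 = t1, t2 = t2)
}
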