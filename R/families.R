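# V gene family clustering at a nucleotide-identity threshold, consensus
# construction via center-star multiple alignment, and the gene naming /
# numbering scheme.

#' Consensus of pre-aligned (gapped) sequences
#'
#' Per-column plurality base with alphabetic tie-break; columns in which gaps
#' form the majority are dropped from the consensus.
#'
#' @param aligned character vector of equal-length gapped rows.
#' @return consensus DNA string.
#' @examples
#' consensusSequence(c("ACGT", "ACGT", "ACGA"))
#' consensusSequence(c("AC-T", "AC-T"))
#' @export
consensusSequence <- function(aligned) {
  stopifnot(is.character(aligned), length(aligned) >= 1L)
  if (length(unique(nchar(aligned))) != 1L)
    stop("aligned rows must have equal length (ragged input)")
  if (nchar(aligned[1L]) == 0L) return("")
  m <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  cols <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    nGap <- sum(col == "-")
    if (nGap > length(col) / 2) return("")
    tab <- table(col[col != "-"])
    best <- max(tab)
    sort(names(tab)[tab == best])[1L]
  }, character(1L))
  paste(cols, collapse = "")
}

# Center-star multiple alignment using the match-maximizing pairwise
# alignment. The center is the sequence with the greatest summed LCS to the
# others (ties: lexicographically smallest sequence, then name). Returns
# gapped rows in input order.
centerStarAlign <- function(seqs) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_len(n))
  if (n == 1L) return(stats::setNames(unname(seqs), names(seqs)))
  score <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sc <- .lcs_length_cpp(seqs[[i]], seqs[[j]])
    score[i, j] <- sc; score[j, i] <- sc
  }
  tot <- rowSums(score)
  cand <- which(tot == max(tot))
  center <- cand[order(unname(seqs[cand]), names(seqs)[cand])][1L]
  C <- seqs[[center]]
  L <- nchar(C)
  others <- setdiff(seq_len(n), center)
  aln <- lapply(others, function(i) .lcs_align_cpp(C, seqs[[i]]))
  # gaps inserted into the center, per slot 0..L (before pos 1 ... after L)
  insPer <- lapply(aln, function(a) {
    gc <- strsplit(a[[1L]], "", fixed = TRUE)[[1L]]
    ins <- integer(L + 1L)
    k <- 0L
    for (ch in gc) {
      if (ch == "-") ins[k + 1L] <- ins[k + 1L] + 1L else k <- k + 1L
    }
    ins
  })
  ins <- Reduce(pmax, insPer, accumulate = FALSE)
  rebuild <- function(gc, gs) {
    # walk the pairwise alignment, padding each slot to the global gap count
    out <- character(0)
    k <- 0L
    buf <- character(0)
    gcv <- strsplit(gc, "", fixed = TRUE)[[1L]]
    gsv <- strsplit(gs, "", fixed = TRUE)[[1L]]
    for (t in seq_along(gcv)) {
      if (gcv[t] == "-") buf <- c(buf, gsv[t])
      else {
        out <- c(out, buf, rep("-", ins[k + 1L] - length(buf)), gsv[t])
        buf <- character(0)
        k <- k + 1L
      }
    }
    out <- c(out, buf, rep("-", ins[L + 1L] - length(buf)))
    paste(out, collapse = "")
  }
  rows <- stats::setNames(vector("character", n), names(seqs))
  centerRow <- character(0)
  Cv <- strsplit(C, "", fixed = TRUE)[[1L]]
  for (k in 0:L) {
    centerRow <- c(centerRow, rep("-", ins[k + 1L]),
                   if (k < L) Cv[k + 1L] else character(0))
  }
  rows[center] <- paste(centerRow, collapse = "")
  for (idx in seq_along(others))
    rows[others[idx]] <- rebuild(aln[[idx]][[1L]], aln[[idx]][[2L]])
  rows
}

roundId <- function(x) round(x, 1L)

#' Cluster V genes into families by nucleotide identity to a consensus
#'
#' Clusters are seeded by single linkage on pairwise percent identity at the
#' threshold, then refined iteratively: each cluster's consensus is rebuilt
#' (center-star multiple alignment + [consensusSequence()]) and genes are
#' reassigned to the consensus with the highest identity, to a fixed point
#' (bounded iterations). Genes below threshold against every consensus form
#' singleton families unless listed in `waivers`, in which case they join
#' their best family with a waiver note (mirroring documented sub-threshold
#' assignments). Threshold comparisons use identities rounded to one decimal.
#'
#' @param genes named [Biostrings::DNAStringSet] or named character vector of
#'   gene nucleotide sequences (one chain/locus).
#' @param threshold percent identity for family membership (default 75).
#' @param waivers gene ids exempt from the threshold.
#' @param maxIter refinement iteration bound.
#' @return list with `members` (data.frame: `gene`, `family` index,
#'   `identity` to the final family consensus, `waiver`) and `consensus`
#'   (named character vector, one per family).
#' @export
clusterFamilies <- function(genes, threshold = 75, waivers = character(0),
                            maxIter = 10L) {
  if (methods::is(genes, "DNAStringSet")) genes <- as.character(genes)
  stopifnot(is.character(genes), length(genes) >= 1L, !is.null(names(genes)))
  genes <- toupper(genes)
  core <- genes[!names(genes) %in% waivers]
  if (length(core) == 0L) stop("all genes are waivers; nothing to cluster")
  n <- length(core)
  pid <- matrix(100, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- roundId(percentIdentity(core[[i]], core[[j]]))
    pid[i, j] <- p; pid[j, i] <- p
  }
  # single-linkage seeding (union-find)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (pid[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  assign <- vapply(seq_len(n), find, integer(1L))
  assign <- match(assign, sort(unique(assign)))
  for (iter in seq_len(maxIter)) {
    consensi <- vapply(sort(unique(assign)), function(k) {
      consensusSequence(centerStarAlign(core[assign == k]))
    }, character(1L))
    newAssign <- integer(n)
    nextSingleton <- length(consensi)
    for (i in seq_len(n)) {
      ids <- roundId(vapply(consensi, function(cs)
        percentIdentity(core[[i]], cs), numeric(1L)))
      best <- which(ids == max(ids))[1L]
      if (ids[best] >= threshold) newAssign[i] <- best
      else {
        nextSingleton <- nextSingleton + 1L
        newAssign[i] <- nextSingleton
      }
    }
    newAssign <- match(newAssign, sort(unique(newAssign)))
    if (identical(newAssign, assign)) break
    assign <- newAssign
  }
  # deterministic family order, independent of input order
  consensi <- vapply(sort(unique(assign)), function(k)
    consensusSequence(centerStarAlign(core[assign == k])), character(1L))
  keyOf <- vapply(sort(unique(assign)), function(k)
    paste(consensi[k], sort(names(core)[assign == k])[1L]), character(1L))
  ord <- order(keyOf)
  remap <- match(seq_along(ord), ord)
  assign <- remap[assign]
  consensi <- consensi[ord]
  members <- data.frame(
    gene = names(core), family = assign,
    identity = roundId(vapply(seq_len(n), function(i)
      percentIdentity(core[[i]], consensi[assign[i]]), numeric(1L))),
    waiver = FALSE, stringsAsFactors = FALSE)
  for (w in intersect(waivers, names(genes))) {
    ids <- roundId(vapply(consensi, function(cs)
      percentIdentity(genes[[w]], cs), numeric(1L)))
    best <- which(ids == max(ids))[1L]
    members <- rbind(members, data.frame(
      gene = w, family = best, identity = ids[best], waiver = TRUE,
      stringsAsFactors = FALSE))
  }
  members <- members[match(names(genes), members$gene), , drop = FALSE]
  rownames(members) <- NULL
  list(members = members, consensus = stats::setNames(
    consensi, paste0("family", seq_along(consensi))))
}

#' Name genes by family and genomic order
#'
#' V genes are named `TR{A,B,G,D}V{family}-{k}` with family numbers and
#' member numbers `k` assigned in ascending genomic order from 5' to 3'
#' toward the C gene (i.e. by descending forward-strand coordinate on a
#' reverse-strand locus). J and D genes are numbered `TR*J{k}` / `TR*D{k}` in
#' the same order. Pseudogenes take a `p` prefix and ORFs an `orf` prefix.
#'
#' @param positions named numeric vector of forward-strand start coordinates
#'   (names are gene ids); positions must be unique.
#' @param chain `"TRA"`, `"TRB"`, `"TRG"` or `"TRD"`.
#' @param geneType `"V"`, `"J"` or `"D"`.
#' @param families for V genes, a vector (parallel to `positions`) of family
#'   labels; labels are renumbered by the genomic order of each family's
#'   first member.
#' @param calls optional vector of functionality calls (`F`/`ORF`/`P`).
#' @param towardC `"right"` if the C gene lies at higher forward coordinates,
#'   `"left"` otherwise (reverse-strand locus).
#' @return named character vector of gene names, parallel to `positions`.
#' @export
nameGenes <- function(positions, chain = c("TRA", "TRB", "TRG", "TRD"),
                      geneType = c("V", "J", "D"), families = NULL,
                      calls = NULL, towardC = c("right", "left")) {
  chain <- match.arg(chain)
  geneType <- match.arg(geneType)
  towardC <- match.arg(towardC)
  stopifnot(!is.null(names(positions)))
  if (anyDuplicated(positions))
    stop("duplicate gene positions: ",
         names(positions)[duplicated(positions)][1L])
  ord <- order(positions, decreasing = (towardC == "left"))
  prefix <- rep("", length(positions))
  if (!is.null(calls)) {
    prefix[calls == "ORF"] <- "orf"
    prefix[calls == "P"] <- "p"
  }
  out <- character(length(positions))
  if (geneType == "V") {
    if (is.null(families)) families <- rep(1L, length(positions))
    famOrder <- unique(families[ord])
    famNum <- match(families, famOrder)
    k <- integer(length(positions))
    for (f in unique(famNum)) {
      idx <- ord[famNum[ord] == f]
      k[idx] <- seq_along(idx)
    }
    out <- paste0(prefix, chain, "V", famNum, "-", k)
  } else {
    k <- integer(length(positions))
    k[ord] <- seq_along(ord)
    out <- paste0(prefix, chain, geneType, k)
  }
  stats::setNames(out, names(positions))
}
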