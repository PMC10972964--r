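# One planted defect per gene, classified on the stated (truth) interval:
# the confusion matrix must be exactly diagonal.

classifyTruthRow <- function(loc, i, ...) {
  tr <- loc$truth
  if (tr$gene_type[i] == "V") {
    classifyV(evaluateVRegion(loc$seq, tr$start[i], tr$end[i], tr$strand[i],
                              leaderMode = tr$leader_mode[i]), ...)
  } else {
    classifyJ(evaluateJRegion(loc$seq, tr$start[i], tr$end[i], tr$strand[i],
                              coreOffset = tr$core_offset[i]), ...)
  }
}

test_that("each planted defect maps to its mandated call and reason", {
  defects <- c(V2 = "stop_codon", V3 = "no_cac", V4 = "missing_anchor",
               V5 = "missing_first_cys",
               J2 = "stop_codon", J3 = "no_cac", J4 = "missing_fg")
  expected <- list(
    none = list(call = "F", reason = character(0)),
    stop_codon = list(call = "P", reason = "stop_codon"),
    no_cac = list(call = "P", reason = "rss_no_cac"),
    missing_anchor = list(call = "ORF", reason = "missing_second_cys_motif"),
    missing_first_cys = list(call = "ORF", reason = "missing_first_cys"),
    missing_fg = list(call = "ORF", reason = "missing_fg"),
    missing_donor = list(call = "ORF", reason = "no_splice_donor"),
    missing_trp = list(call = "ORF", reason = "missing_trp"))
  loc <- simulateLocus(locusSpec(defects = defects, seed = 7L))
  for (i in seq_len(nrow(loc$truth))) {
    res <- classifyTruthRow(loc, i)
    exp <- expected[[loc$truth$defect[i]]]
    expect_identical(res$call, exp$call, info = loc$truth$gene_id[i])
    expect_true(all(exp$reason %in% res$reasons),
                info = loc$truth$gene_id[i])
  }
  loc2 <- simulateLocus(locusSpec(
    defects = c(J1 = "missing_donor", V1 = "missing_trp"), seed = 9L))
  for (i in which(loc2$truth$defect != "none")) {
    res <- classifyTruthRow(loc2, i)
    exp <- expected[[loc2$truth$defect[i]]]
    expect_identical(res$call, exp$call)
    expect_identical(res$reasons, exp$reason)
  }
})

test_that("external hooks demote otherwise functional genes to ORF", {
  loc <- simulateLocus(locusSpec(seed = 11L))
  i <- which(loc$truth$gene_id == "V1")
  lowScore <- function(heptamer, spacer, nonamer) -40
  cfg <- vdjConfig(rssScoreThreshold = -20)
  res <- classifyTruthRow(loc, i, rssScoreHook = lowScore, config = cfg)
  expect_identical(res$call, "ORF")
  expect_identical(res$reasons, "rss_low_score")

  spFail <- function(leader) list(pass = FALSE)
  res2 <- classifyTruthRow(loc, i, signalPeptideHook = spFail)
  expect_identical(res2$call, "ORF")
  expect_identical(res2$reasons, "no_signal_peptide")

  # without hooks the same gene is functional (offline-reproducible default)
  expect_identical(classifyTruthRow(loc, i)$call, "F")
  # hook without threshold is a configuration error
  expect_error(classifyTruthRow(loc, i, rssScoreHook = lowScore),
               "rssScoreThreshold")
})

test_that("classification is pure: candidate order never changes calls", {
  loc <- simulateLocus(locusSpec(defects = c(V2 = "stop_codon"), seed = 3L))
  v <- scanVGenes(loc$seq)
  calls1 <- classifyCandidates(v, seq = loc$seq)
  perm <- rev(seq_along(v))
  calls2 <- classifyCandidates(v[perm], seq = loc$seq)
  expect_identical(calls1$call[perm], calls2$call)
  # F implies a stop-free translation
  expect_false(any(grepl("*", S4Vectors::mcols(v)$protein[
    calls1$call == "F"], fixed = TRUE)))
})

test_that("classifyV/classifyJ enforce the gene-type contract", {
  loc <- simulateLocus(locusSpec(seed = 2L))
  tr <- loc$truth
  iV <- which(tr$gene_type == "V")[1L]
  recV <- evaluateVRegion(loc$seq, tr$start[iV], tr$end[iV], tr$strand[iV],
                          leaderMode = tr$leader_mode[iV])
  expect_error(classifyJ(recV), "J candidate")
  iJ <- which(tr$gene_type == "J")[1L]
  recJ <- evaluateJRegion(loc$seq, tr$start[iJ], tr$end[iJ], tr$strand[iJ])
  expect_error(classifyV(recJ), "V candidate")
})

test_that("V bounds run from cleavage site to the base before the RSS CAC", {
  loc <- simulateLocus(locusSpec(seed = 21L))
  v <- scanVGenes(loc$seq)
  i <- which(as.character(GenomicRanges::strand(v)) == "+")[1L]
  cand <- v[i]
  # candidate already ends at the base before the CAC
  expect_equal(GenomicRanges::end(cand),
               S4Vectors::mcols(cand)$rss_start - 1L)
  cleaved <- defineVBounds(cand, cleavagePos = GenomicRanges::start(cand) +
                             57L)
  expect_equal(GenomicRanges::start(cleaved),
               GenomicRanges::start(cand) + 57L)
  expect_equal(GenomicRanges::end(cleaved), GenomicRanges::end(cand))
  # fallback without cleavage: the candidate's own start
  expect_identical(GenomicRanges::ranges(defineVBounds(cand)),
                   GenomicRanges::ranges(cand))
  noRss <- cand
  S4Vectors::mcols(noRss)$rss_start <- NA_integer_
  expect_error(defineVBounds(noRss), "no RSS")
})
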