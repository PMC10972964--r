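miniTable <- function() {
  data.frame(
    sample_id = c("S1", "S1"), chain = "TRA",
    v_call = c("TRAV1-1", "TRAV2-1"), j_call = c("TRAJ1", "TRAJ1"),
    cdr3 = c("TGTGCTGGG", "TGTGCTTTT"), cdr3_aa = c("CAG", "CAF"),
    umi_count = c(3L, 1L), stringsAsFactors = FALSE)
}

test_that("downsampling equalizes per-sample UMI totals, reproducibly", {
  df <- do.call(rbind, lapply(seq_along(c(100L, 80L, 120L)), function(i) {
    tot <- c(100L, 80L, 120L)[i]
    data.frame(sample_id = paste0("S", i), chain = "TRA",
               v_call = "V", j_call = "J",
               cdr3 = replicate(20, randDna(9)),
               cdr3_aa = "CAG", umi_count = rep(tot %/% 20L, 20L),
               stringsAsFactors = FALSE)
  }))
  set.seed(1)
  ds <- downsampleClonotypes(df, seed = 11L)
  totals <- tapply(ds$umi_count, ds$sample_id, sum)
  expect_true(all(totals == 80L))
  expect_identical(downsampleClonotypes(df, seed = 11L), ds)
  one <- df[df$sample_id == "S1", ]
  expect_identical(downsampleClonotypes(one, seed = 2L)$umi_count,
                   one$umi_count)
  expect_error(downsampleClonotypes(df[0, , drop = FALSE]), "empty")
})

test_that("usage and pairing are UMI-weighted frequencies", {
  up <- usageAndPairing(miniTable())
  expect_equal(up$v_usage, c(`TRAV1-1` = 0.75, `TRAV2-1` = 0.25))
  expect_equal(up$j_usage, c(TRAJ1 = 1))
  expect_equal(sum(up$vj$freq), 1)
  expect_error(usageAndPairing(miniTable()[0, ]), "empty")
  # unassigned calls group under "other"
  df <- miniTable(); df$v_call[2] <- ""
  expect_true("other" %in% names(usageAndPairing(df)$v_usage))
})

test_that("spectratype sums weighted frequencies per CDR3 length", {
  df <- data.frame(sample_id = "S1", chain = "TRA", v_call = "V",
                   j_call = "J", cdr3 = c("A", "A", "A"),
                   cdr3_aa = c(strrep("G", 13), strrep("G", 14),
                               strrep("A", 14)),
                   umi_count = c(2L, 5L, 3L), stringsAsFactors = FALSE)
  sp <- spectratype(df)
  expect_equal(sp, c(`13` = 0.2, `14` = 0.8))
  one <- df[1, ]
  expect_equal(spectratype(one), c(`13` = 1))
})

test_that("publicity classifies by presence across samples", {
  mk <- function(s, aa) data.frame(
    sample_id = s, chain = "TRG", v_call = "V", j_call = "J",
    cdr3 = "TGT", cdr3_aa = aa, umi_count = 1L, stringsAsFactors = FALSE)
  df <- rbind(mk("S1", "PUB"), mk("S2", "PUB"), mk("S3", "PUB"),
              mk("S1", "PRIV1"), mk("S2", "PRIV2"), mk("S3", "PRIV3"))
  pub <- publicity(df)
  cls <- pub$classification
  expect_equal(cls$n_samples[grepl("PUB", cls$key)], 3L)
  expect_true(all(cls$n_samples[grepl("PRIV", cls$key)] == 1L))
  expect_equal(unname(rowSums(pub$shares)), rep(1, 3))
  expect_equal(unname(pub$shares[, "3"]), rep(0.5, 3))
  expect_error(publicity(mk("S1", "X")), "two samples")
})

test_that("publicity and convergence are invariant to row order", {
  rep <- simulateRepertoire(repertoireSpec(nClonotypes = 300L, seed = 2L))
  df <- rep$tables
  set.seed(1)
  shuf <- df[sample(nrow(df)), ]
  p1 <- publicity(df); p2 <- publicity(shuf)
  expect_equal(p1$shares, p2$shares[rownames(p1$shares), , drop = FALSE])
  c1 <- convergence(df); c2 <- convergence(shuf)
  expect_identical(c1[order(names(c1))], c2[order(names(c2))])
})

test_that("convergence counts distinct nucleotide encodings", {
  df <- data.frame(sample_id = "S1", chain = "TRA", v_call = "V",
                   j_call = "J",
                   cdr3 = c("TGTGCT", "TGCGCT", "AAAGGG"),
                   cdr3_aa = c("CA", "CA", "KG"),
                   umi_count = 1L, stringsAsFactors = FALSE)
  cv <- convergence(df)
  expect_equal(cv[["CA"]], 2L)
  expect_equal(cv[["KG"]], 1L)
  expect_true(all(convergence(miniTable()) == 1L))
})

test_that("rank-abundance groups share the repertoire at given boundaries", {
  df <- data.frame(sample_id = "S1", chain = "TRA", v_call = "V",
                   j_call = "J", cdr3 = paste0("C", 1:4),
                   cdr3_aa = paste0("A", 1:4),
                   umi_count = c(4L, 3L, 2L, 1L), stringsAsFactors = FALSE)
  ra <- rankAbundance(df, boundaries = 2L)
  expect_equal(unname(ra), c(0.7, 0.3))
  expect_identical(names(ra), c("1-2", "3+"))
  expect_equal(sum(rankAbundance(df)), 1)
})

test_that("amino-acid composition averages counts per CDR3", {
  df <- data.frame(sample_id = "S1", chain = "TRA", v_call = "V",
                   j_call = "J", cdr3 = "GGAGGTGCA", cdr3_aa = "GGA",
                   umi_count = 1L, stringsAsFactors = FALSE)
  comp <- aaComposition(df)
  expect_equal(comp[["G"]], 2)
  expect_equal(comp[["A"]], 1)
  expect_equal(comp[["Y"]], 0)
})

test_that("chimeras are V calls from another chain's locus", {
  df <- data.frame(sample_id = "S1", chain = "TRD",
                   v_call = c("TRDV1-2", "TRAV2-3", "orfTRDV4-1", "pTRAV1-9"),
                   j_call = "TRDJ1", cdr3 = "TGT", cdr3_aa = "C",
                   umi_count = 1L, stringsAsFactors = FALSE)
  expect_identical(flagChimeras(df), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("non-expressed clonotypes are excluded with a logged count", {
  df <- miniTable()
  df$cdr3_aa[1] <- "C*G"
  df <- rbind(df, within(miniTable()[1, ], cdr3 <- "TGTG"))
  out <- filterProductive(df)
  expect_equal(attr(out, "n_excluded"), 2L)
  expect_equal(nrow(out), 1L)
})

test_that("repertoireSummary recovers planted generator structure", {
  rep <- simulateRepertoire(repertoireSpec(nClonotypes = 2000L, seed = 5L))
  rs <- repertoireSummary(rep$tables, downsample = TRUE, seed = 5L)
  expect_s4_class(rs, "RepertoireSummary")
  expect_lt(totalVariation(vUsage(rs), rep$truth$vUsage), 0.06)
  expect_equal(max(rs@convergence), 12L)
  expect_equal(sum(spectratype(rs)), 1)
  sp <- spectratype(rs)
  expect_true(names(sp)[which.max(sp)] %in% c("14", "15"))
  expect_output(show(rs), "RepertoireSummary")
})
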