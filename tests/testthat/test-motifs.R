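test_that("findRss accepts 12/23 spacers with +/- 1 tolerance only", {
  # V side: CAC + spacer + nonamer downstream of the gene (23-class)
  for (sp in 20:26) {
    seq <- paste0(strrep("G", 20), makeFlank(sp))
    hits <- findRss(seq, 20L, "downstream_of_v")
    if (abs(sp - 23L) <= 1L) {
      expect_equal(hits$spacer_len, sp)
      expect_equal(hits$cac_pos, 21L)
      expect_equal(hits$spacer_class, 23L)
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
  # J side: the same layout read away from the gene on the reverse strand
  for (sp in 9:15) {
    flank <- makeFlank(sp)
    jseq <- paste0(strrep("G", 5), revComp(flank), "TTCGGCACAGG")
    geneStart <- 5L + nchar(flank) + 1L
    hits <- findRss(jseq, geneStart, "upstream_of_j")
    if (abs(sp - 12L) <= 1L) {
      expect_equal(hits$spacer_len, sp)
      expect_equal(hits$spacer_class, 12L)
      expect_identical(hits$side, "five_prime")
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
})

test_that("findRss requires a literal CAC at the boundary", {
  seq <- paste0(strrep("G", 20), "AAC", strrep("TG", 12) |> substr(1, 23),
                "ACAAAAACC")
  expect_equal(nrow(findRss(seq, 20L, "downstream_of_v")), 0L)
  set.seed(42)
  for (i in 1:50) {
    s <- randDna(80)
    hits <- findRss(s, 40L, "downstream_of_v")
    if (nrow(hits) > 0L)
      expect_identical(substr(s, hits$cac_pos[1], hits$cac_pos[1] + 2L),
                       "CAC")
  }
})

test_that("findRss records the nonamer and returns empty off-sequence", {
  seq <- paste0(strrep("G", 10), makeFlank(23L))
  hits <- findRss(seq, 10L, "downstream_of_v")
  expect_identical(hits$nonamer, "ACAAAAACC")
  expect_identical(hits$side, "three_prime")
  expect_equal(nrow(findRss(seq, nchar(seq), "downstream_of_v")), 0L)
})

test_that("conserved V anchors are located within their windows", {
  filler <- function(k) strrep("G", k)
  prot <- paste0(filler(24), "C", filler(14), "W", filler(59), "YYC",
                 filler(10))
  hits <- findConservedVAnchors(prot)
  expect_setequal(hits$name,
                  c("first_cys", "conserved_trp", "second_cys_motif"))
  expect_equal(hits$pos[hits$name == "first_cys"], 25L)
  expect_equal(hits$pos[hits$name == "conserved_trp"], 40L)
  expect_equal(hits$pos[hits$name == "second_cys_motif"], 100L)

  noW <- gsub("W", "G", prot, fixed = TRUE)
  expect_false("conserved_trp" %in% findConservedVAnchors(noW)$name)
  # second-cys motif is still reported when the first cys is absent
  noC1 <- paste0(filler(24), "S", substr(prot, 26, nchar(prot)))
  hitsNoC <- findConservedVAnchors(noC1)
  expect_false("first_cys" %in% hitsNoC$name)
  expect_true("second_cys_motif" %in% hitsNoC$name)

  tfc <- paste0(filler(24), "C", filler(14), "W", filler(59), "TFC",
                filler(10))
  h <- findConservedVAnchors(tfc)
  expect_identical(h$matched_text[h$name == "second_cys_motif"], "TFC")
})

test_that("rightmost second-cys motif inside the window wins", {
  filler <- function(k) strrep("G", k)
  prot <- paste0(filler(24), "C", filler(14), "W", filler(44), "YFC",
                 filler(12), "YYC", filler(10))
  h <- findConservedVAnchors(prot)
  expect_identical(h$matched_text[h$name == "second_cys_motif"], "YYC")
  expect_equal(h$pos[h$name == "second_cys_motif"], 100L)
})

test_that("J anchors: core with FG frame, secondary motif, splice donor", {
  h <- findJAnchors("TTCGGCACAGG")
  expect_equal(h$pos[h$name == "j_core"], 1L)
  expect_true("fg_motif" %in% h$name)
  expect_identical(substr(translateDNA("TTCGGCACAGG"), 1, 2), "FG")
  expect_false("j_core" %in% findJAnchors("TTAGGCACAGG")$name)
  expect_equal(findJAnchors("GTAAGA")$name, c("splice_donor"))
  expect_true("j_secondary" %in% findJAnchors("TCACCGT")$name)
})
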