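test_that("planted V and J genes are recovered at exact coordinates", {
  loc <- simulateLocus(locusSpec(seed = 42L))
  v <- scanVGenes(loc$seq)
  j <- scanJGenes(loc$seq)
  expectExactRecovery(v, loc$truth, "V")
  expectExactRecovery(j, loc$truth, "J")
  tv <- loc$truth[loc$truth$gene_type == "V", ]
  expect_identical(S4Vectors::mcols(v)$leader_mode, tv$leader_mode)
  # proteins carry the planted anchors
  mc <- S4Vectors::mcols(v)
  expect_true(all(!is.na(mc$first_cys_aa) & !is.na(mc$trp_aa) &
                    !is.na(mc$second_cys_aa)))
  expect_false(any(grepl("*", mc$protein, fixed = TRUE)))
})

test_that("no V candidates survive when every CAC is ablated", {
  set.seed(77)
  s <- randDna(100000)
  while (grepl("CAC", s, fixed = TRUE)) s <- sub("CAC", "CTC", s, fixed = TRUE)
  expect_length(scanVGenes(stats::setNames(s, "bg")), 0L)
})

test_that("a mutated second-cys motif removes the candidate", {
  loc <- simulateLocus(locusSpec(defects = c(V2 = "missing_anchor"),
                                 seed = 13L))
  v <- scanVGenes(loc$seq)
  expectExactRecovery(v, loc$truth, "V")   # only defect-free genes found
  expect_equal(length(v), 4L)
})

test_that("J scanning applies spacer tolerance and stop exclusion", {
  loc <- simulateLocus(locusSpec(
    defects = c(J1 = "stop_codon", J2 = "spacer_out_of_tolerance"),
    seed = 19L))
  j <- scanJGenes(loc$seq)
  expectExactRecovery(j, loc$truth, "J")
  expect_equal(length(j), 2L)
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  loc <- simulateLocus(locusSpec(seed = 5L))
  s <- as.character(loc$seq)[[1L]]
  n <- nchar(s)
  for (scan in list(scanVGenes, scanJGenes)) {
    fwd <- scan(stats::setNames(s, "x"))
    rev <- scan(stats::setNames(revComp(s), "x"))
    expect_equal(sort(n - GenomicRanges::end(rev) + 1L),
                 sort(GenomicRanges::start(fwd)))
    expect_equal(sort(n - GenomicRanges::start(rev) + 1L),
                 sort(GenomicRanges::end(fwd)))
    flip <- c(`+` = "-", `-` = "+")
    expect_setequal(paste(n - GenomicRanges::end(rev) + 1L,
                          flip[as.character(GenomicRanges::strand(rev))]),
                    paste(GenomicRanges::start(fwd),
                          as.character(GenomicRanges::strand(fwd))))
  }
})

test_that("output is deterministic and sorted by sequence, start, strand", {
  loc <- simulateLocus(locusSpec(seed = 23L))
  v1 <- scanVGenes(loc$seq)
  v2 <- scanVGenes(loc$seq)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_false(is.unsorted(GenomicRanges::start(v1)))
})

test_that("D segments require flanking 12- and 23-RSS and an open frame", {
  set.seed(3)
  d <- buildDCassette()
  s <- stats::setNames(paste0(sampleBackground(200), d$seq,
                              sampleBackground(200)), "w")
  dc <- scanDSegments(s, c(150L, 320L))
  expect_equal(GenomicRanges::start(dc), 200L + d$gene_start)
  expect_equal(GenomicRanges::end(dc), 200L + d$gene_end)
  expect_equal(GenomicRanges::width(dc), 12L)

  # stop codon in frame 0 only: still reported, with per-frame openness
  d2 <- buildDCassette("TAAACAGGGGGC")
  s2 <- stats::setNames(paste0(sampleBackground(200), d2$seq,
                               sampleBackground(200)), "w")
  dc2 <- scanDSegments(s2, c(150L, 320L))
  expect_equal(length(dc2), 1L)
  expect_false(grepl("0", S4Vectors::mcols(dc2)$notes))
  expect_true(grepl("frames_open=1,2", S4Vectors::mcols(dc2)$notes))

  expect_length(scanDSegments(s, c(1L, 100L)), 0L)
  expect_error(scanDSegments(s), "window")
})

test_that("family motifs near the mature 5' end assign V families", {
  expect_identical(assignFamily("QVQQGGGGGGGG"), "TRAV1")
  expect_identical(assignFamily("GGQAAPVQGGGG"), "TRGV3")
  expect_identical(assignFamily("GGGGGGGGGGGG"), NA_character_)
  # motif beyond the window is not assigned
  expect_identical(assignFamily(paste0(strrep("G", 20), "QVQQ")),
                    NA_character_)
  # single-exon proteins keep the leader, so the window is extended
  expect_identical(assignFamily(paste0(strrep("G", 20), "QVQQ"),
                                leaderMode = "single_exon"), "TRAV1")
})
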