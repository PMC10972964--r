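test_that("end-to-end annotation recovers planted truth with names", {
  loc <- simulateLocus(locusSpec(seed = 42L))
  gs <- runAnnotate(loc$seq, chain = "TRA", towardC = "left")
  expect_s4_class(gs, "GermlineSet")
  expectExactRecovery(
    candidates(gs)[S4Vectors::mcols(candidates(gs))$gene_type == "V"],
    loc$truth, "V")
  expectExactRecovery(
    candidates(gs)[S4Vectors::mcols(candidates(gs))$gene_type == "J"],
    loc$truth, "J")
  expect_true(all(functionality(gs)$call == "F"))
  expect_true(all(grepl("^TRA[VJ]", geneNames(gs))))
  # J numbering ascends toward the C gene (left of this locus)
  jn <- geneNames(gs)[S4Vectors::mcols(candidates(gs))$gene_type == "J"]
  expect_identical(jn, paste0("TRAJ", rev(seq_along(jn))))
  expect_output(show(gs), "GermlineSet")
  expect_equal(gs@log$n_f, 9L)
})

test_that("annotation of an empty input exits cleanly", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), path)
  gs <- runAnnotate(path)
  expect_length(candidates(gs), 0L)
  expect_length(geneNames(gs), 0L)
})

test_that("germline export keeps F and ORF genes, drops pseudogenes", {
  loc <- simulateLocus(locusSpec(seed = 15L))
  gs <- runAnnotate(loc$seq, chain = "TRA")
  # recast two calls to exercise the F+ORF export rule (2 F, 1 ORF -> 3 of 4)
  gs@calls$call[1:2] <- c("ORF", "P")
  dir <- withr::local_tempdir()
  paths <- exportGermlineLibrary(gs, dir)
  fa <- readFasta(paths[["fasta"]])
  expect_equal(length(fa), length(gs@geneNames) - 1L)
  expect_false(gs@geneNames[2] %in% names(fa))
  anchors <- utils::read.delim(paths[["anchors"]])
  expect_equal(nrow(anchors), length(fa))
  vA <- anchors[anchors$gene_type == "V", ]
  expect_true(all(vA$CDR3Begin > vA$FR3Begin & vA$CDR3Begin < vA$VEnd))
  jA <- anchors[anchors$gene_type == "J", ]
  expect_true(all(jA$FR4Begin > jA$JBegin & jA$FR4End > jA$FR4Begin))
  # reruns are byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- exportGermlineLibrary(gs, dir2)
  expect_identical(readLines(paths[["fasta"]]), readLines(paths2[["fasta"]]))
  expect_identical(readLines(paths[["anchors"]]),
                   readLines(paths2[["anchors"]]))
})

test_that("non-monotone anchor overrides are rejected, naming the gene", {
  loc <- simulateLocus(locusSpec(seed = 16L))
  gs <- runAnnotate(loc$seq, chain = "TRA")
  bad <- data.frame(gene_name = gs@geneNames[1], CDR3Begin = 10L)
  expect_error(computeAnchors(gs, overrides = bad),
               paste0("non-monotone.*", gs@geneNames[1]))
})

test_that("waivers admit sub-threshold genes into their best family", {
  loc <- simulateLocus(locusSpec(seed = 18L))
  gs <- runAnnotate(loc$seq, chain = "TRA", waivers = "V2")
  fam <- familyTable(gs)
  expect_true(fam$waiver[fam$gene == "V2"])
  expect_gt(sum(fam$family == fam$family[fam$gene == "V2"]), 1L)
})

test_that("key=value config files round-trip into scanner settings", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "vExonLen = 200, 400", "familyK = 20",
               "relaxJSecondary = TRUE"), path)
  cfg <- readConfig(path)
  expect_equal(cfg$vExonLen, c(200L, 400L))
  expect_equal(cfg$familyK, 20L)
  expect_true(cfg$relaxJSecondary)
  expect_equal(cfg$jLen, vdjConfig()$jLen)
  writeLines("notAKey = 1", path)
  expect_error(readConfig(path), "unknown config key")
  writeLines("vExonLen 200", path)
  expect_error(readConfig(path), "malformed")
})
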