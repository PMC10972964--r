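test_that("consensus takes per-column plurality with documented tie rules", {
  expect_identical(consensusSequence(c("ACGT", "ACGT", "ACGA")), "ACGT")
  expect_identical(consensusSequence(c("AC-T", "AC-T")), "ACT")
  # ties broken alphabetically, column by column
  expect_identical(consensusSequence(c("ACGT", "TGCA")), "ACCA")
  expect_identical(consensusSequence(c("ACGT", "TGCA")),
                   consensusSequence(c("TGCA", "ACGT")))
  # majority-gap columns are dropped
  expect_identical(consensusSequence(c("A--T", "A-CT", "AGCT")), "ACT")
  expect_error(consensusSequence(c("ACGT", "ACG")), "ragged")
})

test_that("two mutation families are recovered exactly", {
  for (seed in c(1L, 2L, 3L)) {
    fx <- twoTemplateGenes(seed)
    cl <- clusterFamilies(fx$genes)
    expect_equal(length(cl$consensus), 2L)
    byFam <- split(fx$labels, cl$members$family[match(names(fx$genes),
                                                      cl$members$gene)])
    expect_true(all(vapply(byFam, function(x) length(unique(x)) == 1L,
                           logical(1L))))
    expect_true(all(cl$members$identity >= 75))
  }
})

test_that("a single gene forms a singleton family at 100% identity", {
  cl <- clusterFamilies(c(g = randDna(300)))
  expect_equal(nrow(cl$members), 1L)
  expect_equal(cl$members$identity, 100)
  expect_equal(cl$members$family, 1L)
})

test_that("sub-threshold outliers are singletons unless waived", {
  set.seed(31)
  fx <- twoTemplateGenes(31L)
  outlier <- mutateSeq(fx$t1, 120L)   # ~60% to template 1
  genes <- c(fx$genes, out = outlier)
  cl <- clusterFamilies(genes)
  outFam <- cl$members$family[cl$members$gene == "out"]
  expect_equal(sum(cl$members$family == outFam), 1L)
  clW <- clusterFamilies(genes, waivers = "out")
  outFamW <- clW$members$family[clW$members$gene == "out"]
  expect_gt(sum(clW$members$family == outFamW), 1L)
  expect_true(clW$members$waiver[clW$members$gene == "out"])
  expect_lt(clW$members$identity[clW$members$gene == "out"], 75)
})

test_that("clustering is invariant to input order", {
  fx <- twoTemplateGenes(17L)
  cl1 <- clusterFamilies(fx$genes)
  set.seed(5)
  perm <- sample(length(fx$genes))
  cl2 <- clusterFamilies(fx$genes[perm])
  a <- cl1$members[order(cl1$members$gene), ]
  b <- cl2$members[order(cl2$members$gene), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_identical(cl1$consensus, cl2$consensus)
})

test_that("reported identities match an independent recomputation", {
  fx <- twoTemplateGenes(9L)
  cl <- clusterFamilies(fx$genes)
  for (i in seq_len(nrow(cl$members))) {
    g <- fx$genes[[cl$members$gene[i]]]
    cs <- cl$consensus[[cl$members$family[i]]]
    expect_equal(cl$members$identity[i], round(percentIdentity(g, cs), 1))
  }
})

test_that("genes are named by family and genomic order toward the C gene", {
  # reverse-strand locus: C gene to the left, k ascends with decreasing
  # forward coordinate
  pos <- stats::setNames(c(5000, 3000, 1000), c("g1", "g2", "g3"))
  nm <- nameGenes(pos, chain = "TRA", geneType = "V",
                  families = c(1L, 1L, 1L), towardC = "left")
  expect_identical(unname(nm), c("TRAV1-1", "TRAV1-2", "TRAV1-3"))
  nmC <- nameGenes(pos, chain = "TRA", geneType = "V",
                   families = c(1L, 1L, 1L),
                   calls = c("F", "ORF", "P"), towardC = "left")
  expect_identical(unname(nmC), c("TRAV1-1", "orfTRAV1-2", "pTRAV1-3"))
  # singleton family keeps the -1 suffix
  nm1 <- nameGenes(stats::setNames(10, "only"), chain = "TRA",
                   geneType = "V", families = 3L)
  expect_identical(unname(nm1), "TRAV1-1")
  # J genes numbered in the same order, no family component
  nmJ <- nameGenes(pos, chain = "TRG", geneType = "J", towardC = "left")
  expect_identical(unname(nmJ), c("TRGJ1", "TRGJ2", "TRGJ3"))
  expect_error(nameGenes(stats::setNames(c(1, 1), c("a", "b")),
                         chain = "TRA", geneType = "V"), "duplicate")
})

test_that("family numbering follows the genomic order of first members", {
  pos <- stats::setNames(c(100, 200, 300, 400), paste0("g", 1:4))
  nm <- nameGenes(pos, chain = "TRB", geneType = "V",
                  families = c(2L, 2L, 9L, 2L), towardC = "right")
  expect_identical(unname(nm),
                   c("TRBV1-1", "TRBV1-2", "TRBV2-1", "TRBV1-3"))
})
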