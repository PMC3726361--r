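test_that("simulateDesign produces the requested layout deterministically", {
  d <- simulateDesign(7, 3, 7, 2)
  expect_equal(nrow(d), 28)
  expect_equal(sum(d$treatment == "control"), 7)
  expect_equal(as.integer(table(d$treatment)[setdiff(unique(d$treatment),
                                                     "control")]),
               rep(3L, 7))
  expect_false(anyDuplicated(d$sample_id) > 0)

  # minimal design
  d1 <- simulateDesign(1, 1, 1, 1)
  expect_equal(nrow(d1), 2)
  expect_setequal(d1$treatment, c("AMH", "control"))

  # round-robin batch assignment, enumerated by hand
  d2 <- simulateDesign(2, 3, 4, 2, seed = 1)
  expect_equal(nrow(d2), 10)
  expect_equal(d2$batch, rep(c(1L, 2L), 5))

  expect_error(simulateDesign(0, 3, 7, 2), class = "invalidArgumentError")
  expect_identical(simulateDesign(seed = 1), simulateDesign(seed = 2))
})

test_that("degenerate generator gives a constant baseline matrix", {
  d <- simulateDesign(2, 2, 2, 1)
  se <- simulateExpression(d, nGenes = 30, moduleSizes = integer(0),
                           moduleSignalSd = 0, deEffects = NA, batchSd = 0,
                           noiseSd = 0, outlier = FALSE, seed = 1)
  m <- SummarizedExperiment::assay(se)
  expect_true(all(m == 100))
  expect_equal(dim(m), c(30L, 6L))
})

test_that("planted modules correlate more within than between", {
  d <- paperDesign()
  se <- simulateExpression(d, nGenes = 500, moduleSizes = c(240, 209),
                           moduleSignalSd = 20, noiseSd = 10, deEffects = NA,
                           outlier = FALSE, seed = 11)
  cc <- correlationMatrix(se)
  lab <- simulationTruth(se)$module_label
  same <- outer(lab, lab, "==") & outer(lab, lab, function(a, b) a > 0)
  diff <- outer(lab, lab, "!=") & outer(lab, lab, function(a, b) a > 0 & b > 0)
  ut <- upper.tri(cc)
  expect_gt(mean(abs(cc[same & ut])), mean(abs(cc[diff & ut])))
})

test_that("planted treatment effects are recovered by the DE filter", {
  d <- paperDesign()
  genes <- sprintf("g%04d", 1:1000)
  de <- data.frame(treatment = "AMH", gene_id = genes[1:100],
                   effect = 50, fold = 1.5)
  se <- simulateExpression(d, nGenes = 1000, moduleSizes = integer(0),
                           deEffects = de, outlier = FALSE, seed = 4)
  sig <- signatureList(SummarizedExperiment::assay(se), d, "AMH")
  recovered <- intersect(sig$gene_id[sig$passes], genes[1:100])
  expect_gte(length(recovered), 90)
})

test_that("simulated signature overlap matches the configured fraction", {
  d <- paperDesign()
  genes <- sprintf("g%05d", 1:5000)
  de <- simulateDeEffects(d, genes, overlapFrac = 0.08, seed = 9)
  lists <- split(de$gene_id, de$treatment)
  ov <- pairwiseOverlap(lists)
  offdiag <- ov$fraction[upper.tri(ov$fraction)]
  expect_true(all(abs(offdiag - 0.08) <= 0.03))
  # per-treatment shared-with-any fraction
  for (t in names(lists)) {
    others <- unique(unlist(lists[setdiff(names(lists), t)]))
    sharedFrac <- length(intersect(lists[[t]], others)) / length(lists[[t]])
    expect_true(abs(sharedFrac - 0.08) <= 0.03)
  }
  expect_error(simulateDeEffects(d, genes, overlapFrac = 1.5),
               class = "invalidArgumentError")
})

test_that("expression generation is bit-identical for a fixed seed", {
  d <- paperDesign()
  se1 <- simulateExpression(d, nGenes = 200, moduleSizes = c(30, 20), seed = 5,
                            deEffects = NA)
  se2 <- simulateExpression(d, nGenes = 200, moduleSizes = c(30, 20), seed = 5,
                            deEffects = NA)
  expect_identical(SummarizedExperiment::assay(se1),
                   SummarizedExperiment::assay(se2))
  se3 <- simulateExpression(d, nGenes = 200, moduleSizes = c(30, 20), seed = 6,
                            deEffects = NA)
  expect_false(identical(SummarizedExperiment::assay(se1),
                         SummarizedExperiment::assay(se3)))
})

test_that("generator validates its arguments", {
  d <- paperDesign()
  expect_error(simulateExpression(d, nGenes = 10, moduleSizes = c(20)),
               class = "invalidArgumentError")
  expect_error(simulateExpression(d, nGenes = 100, moduleSizes = integer(0),
                                  noiseSd = -1),
               class = "invalidArgumentError")
  expect_error(simulateExpression(d, nGenes = 100, moduleSizes = integer(0),
                                  overlapFrac = 2),
               class = "invalidArgumentError")
})

test_that("fixture bundle round-trips and is reproducible byte-for-byte", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- writeFixtureBundle(dir1, nGenes = 300, seed = 3,
                           moduleSizes = c(40, 30),
                           deEffects = simulateDeEffects(
                             simulateDesign(), sprintf("g%04d", 1:300),
                             sizes = rep(25, 7), seed = 3))
  expect_length(p1, 6)
  expect_true(all(file.exists(p1)))

  # reload losslessly
  m <- readExpression(p1["expression"])
  d <- readDesign(p1["design"])
  expect_equal(dim(m), c(300L, 28L))
  expect_equal(nrow(d), 28)
  ann <- readAnnotation(p1["annotation"])
  expect_equal(nrow(ann), 300)
  sets <- readGMT(p1["gmt"])
  expect_gt(length(sets), 0)
  g <- suppressWarnings(readEdgeList(p1["edges"]))
  expect_gt(nrow(edgeTable(g)), 0)

  p2 <- writeFixtureBundle(dir2, nGenes = 300, seed = 3,
                           moduleSizes = c(40, 30),
                           deEffects = simulateDeEffects(
                             simulateDesign(), sprintf("g%04d", 1:300),
                             sizes = rep(25, 7), seed = 3))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("planted GMT sets are recovered by the enrichment stage", {
  # a set built from 10 genes of which 8 carry planted effects must report
  # overlap 8 against the true signature
  d <- paperDesign()
  genes <- sprintf("g%04d", 1:500)
  de <- data.frame(treatment = "E2", gene_id = genes[1:50], effect = 60,
                   fold = 1.6)
  set <- c(genes[1:8], genes[101:102])
  enr <- enrichGeneSets(genes[1:50], list(planted = set), genes)
  expect_equal(enr$overlap, 8)
  expect_true(enr$impacted)
})
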