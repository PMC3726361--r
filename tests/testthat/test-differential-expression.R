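test_that("identical columns are never flagged and KS threshold 1 never fires", {
  m <- makeExprMatrix(50, 6, sd = 0)
  qc <- flagOutlierArrays(m)
  expect_false(any(qc$flagged))
  expect_true(all(qc$ks_distance == 0))

  m2 <- makeExprMatrix(200, 28, sd = 5, seed = 2)
  qc2 <- flagOutlierArrays(m2, threshold = 1.0)
  expect_false(any(qc2$flagged))
  expect_true(all(qc2$ks_distance <= 1))
})

test_that("a globally scaled array is flagged as an outlier", {
  m <- makeExprMatrix(500, 28, sd = 10, seed = 3)
  m[, "s07"] <- m[, "s07"] * 10
  qc <- flagOutlierArrays(m, threshold = 0.25)
  expect_identical(qc$sample_id[qc$flagged], "s07")
  expect_error(flagOutlierArrays(m[, 1:2]), class = "invalidArgumentError")
})

test_that("batch centering removes a constant offset and preserves grand means", {
  d <- simulateDesign(2, 2, 4, 2)
  m <- makeExprMatrix(40, nrow(d), sd = 3, seed = 4)
  colnames(m) <- d$sample_id
  m0 <- m
  b2 <- d$sample_id[d$batch == 2]
  m[, b2] <- m[, b2] + 5
  centered <- batchCenter(m, d)
  # the +5 offset is removed exactly: batch means equalised per gene
  for (g in 1:5) {
    expect_equal(mean(centered[g, b2]),
                 mean(centered[g, setdiff(colnames(m), b2)]), tolerance = 1e-10)
  }
  expect_equal(rowMeans(centered), rowMeans(m), tolerance = 1e-10)

  # single batch: identity
  d1 <- d; d1$batch <- 1L
  expect_equal(batchCenter(m0, d1), m0, tolerance = 1e-12)

  # singleton batch rejected
  dBad <- d; dBad$batch[1] <- 3L
  expect_error(batchCenter(m, dBad), class = "invalidArgumentError")
})

test_that("signature statistics match t.test and the three-rule evaluation", {
  d <- simulateDesign(1, 3, 7, 1)
  withr::with_seed(10, {
    m <- matrix(100 + rnorm(20 * 10, sd = 8), 20, 10,
                dimnames = list(sprintf("g%03d", 1:20), d$sample_id))
  })
  trt <- d$sample_id[d$treatment == "AMH"]
  ctl <- d$sample_id[d$treatment == "control"]
  m[1:5, trt] <- m[1:5, trt] + 40       # strong planted shift

  sig <- signatureList(m, d, "AMH")
  crit <- deCriteria()
  for (g in c(1, 3, 8, 15)) {
    tt <- t.test(m[g, trt], m[g, ctl])
    expect_equal(sig$p_value[g], tt$p.value, tolerance = 1e-12)
    fc <- mean(m[g, trt]) / mean(m[g, ctl])
    expect_equal(sig$fold_change[g], fc, tolerance = 1e-12)
    manual <- (fc >= crit$fcUp || fc <= crit$fcDown) &&
      tt$p.value <= crit$pMax &&
      abs(mean(m[g, trt]) - mean(m[g, ctl])) >= crit$minAbsDiff
    expect_identical(sig$passes[g], manual)
  }
  # pooled-variance variant matches var.equal t.test
  sigP <- signatureList(m, d, "AMH", varEqual = TRUE)
  ttP <- t.test(m[2, trt], m[2, ctl], var.equal = TRUE)
  expect_equal(sigP$p_value[2], ttP$p.value, tolerance = 1e-12)
})

test_that("boundary fold change 1.2 passes inclusively", {
  d <- simulateDesign(1, 4, 4, 1)
  trt <- d$sample_id[d$treatment != "control"]
  ctl <- d$sample_id[d$treatment == "control"]
  m <- matrix(0, 2, 8, dimnames = list(c("gBoundary", "gFlat"), d$sample_id))
  # tiny within-group jitter, means exactly 100 and 120
  m["gBoundary", ctl] <- c(99.9, 100.1, 99.9, 100.1)
  m["gBoundary", trt] <- c(119.9, 120.1, 119.9, 120.1)
  m["gFlat", ] <- 100
  sig <- signatureList(m, d, d$treatment[1], criteria = deCriteria())
  expect_equal(sig$fold_change[1], 1.2, tolerance = 1e-12)
  expect_equal(sig$abs_diff[1], 20, tolerance = 1e-12)
  expect_true(sig$passes[1])
  # no-effect gene: fold change exactly 1, zero variance in both groups -> p 1
  expect_equal(sig$fold_change[2], 1)
  expect_equal(sig$p_value[2], 1)
  expect_false(sig$passes[2])
})

test_that("zero control mean yields an infinite fold-change marker", {
  d <- simulateDesign(1, 3, 3, 1)
  m <- matrix(1, 2, 6, dimnames = list(c("gA", "gB"), d$sample_id))
  ctl <- d$sample_id[d$treatment == "control"]
  trt <- setdiff(d$sample_id, ctl)
  m["gA", ctl] <- 0
  m["gA", trt] <- c(30, 31, 29)
  sig <- signatureList(m, d, "AMH")
  expect_identical(sig$fold_change[sig$gene_id == "gA"], Inf)
  expect_error(signatureList(m, d, "nope"), class = "keyError")
})

test_that("filter is idempotent and loosening any criterion never shrinks the set", {
  d <- paperDesign()
  se <- simulateExpression(d, nGenes = 400, moduleSizes = integer(0),
                           deEffects = simulateDeEffects(
                             d, sprintf("g%04d", 1:400), sizes = rep(30, 7),
                             seed = 7),
                           outlier = FALSE, seed = 7)
  m <- SummarizedExperiment::assay(se)
  base <- signatureList(m, d, "FGF2")
  passing <- base$gene_id[base$passes]

  # idempotence: re-filtering the passing submatrix flags them all again
  resub <- signatureList(m[passing, , drop = FALSE], d, "FGF2")
  expect_setequal(resub$gene_id[resub$passes], passing)

  looser <- list(deCriteria(fcUp = 1.1, fcDown = 0.83),
                 deCriteria(fcUp = 1.2, fcDown = 0.9),
                 deCriteria(pMax = 0.2),
                 deCriteria(minAbsDiff = 5))
  for (cr in looser) {
    s <- signatureList(m, d, "FGF2", criteria = cr)
    expect_true(all(passing %in% s$gene_id[s$passes]))
  }
})

test_that("union table combines signatures with direction and counts", {
  mk <- function(t, genes, dir) {
    s <- data.frame(gene_id = genes, mean_control = 100, mean_treated = 130,
                    fold_change = ifelse(dir == "up", 1.3, 0.7), p_value = 0.01,
                    abs_diff = 30, direction = dir, passes = TRUE,
                    stringsAsFactors = FALSE)
    attr(s, "treatment") <- t
    s
  }
  # disjoint lists
  u <- unionSignatures(list(A = mk("A", paste0("g", 1:3), "up"),
                            B = mk("B", paste0("g", 4:7), "down")))
  expect_equal(nrow(u), 7)
  expect_true(all(u$n_treatments == 1))

  # identical lists
  u2 <- unionSignatures(list(A = mk("A", paste0("g", 1:3), "up"),
                             B = mk("B", paste0("g", 1:3), "up")))
  expect_equal(nrow(u2), 3)
  expect_true(all(u2$n_treatments == 2))

  # a single gene passing in 4 treatments is the unique argmax
  lists <- lapply(1:4, function(i) {
    mk(paste0("T", i), c("gShared", paste0("g", i, letters[1:2])), "up")
  })
  names(lists) <- paste0("T", 1:4)
  u3 <- unionSignatures(lists)
  expect_equal(max(u3$n_treatments), 4)
  expect_identical(u3$gene_id[u3$n_treatments == 4], "gShared")
})
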