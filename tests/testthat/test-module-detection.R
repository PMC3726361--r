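test_that("average-linkage heights behave on forced structures", {
  # two perfect blocks: block merges at 0, final merge at 1
  w <- makeBlockTOM(c(5, 4), hi = 1, lo = 0)
  hc <- clusterTOM(w)
  expect_equal(max(hc$height), 1, tolerance = 1e-12)
  expect_equal(sort(hc$height)[1:7], rep(0, 7), tolerance = 1e-12)

  # identity TOM: all merges at 1
  id <- diag(6); dimnames(id) <- list(paste0("g", 1:6), paste0("g", 1:6))
  expect_true(all(abs(clusterTOM(id)$height - 1) < 1e-12))

  # merge heights are non-decreasing
  a <- makeRandomAdjacency(15, seed = 3)
  hc2 <- clusterTOM(tomMatrix(topologicalOverlap(a)))
  expect_true(all(diff(hc2$height) >= -1e-12))

  expect_error(clusterTOM(matrix(1, 1, 1, dimnames = list("g", "g"))),
               class = "invalidArgumentError")
})

test_that("hand-run average-linkage trace matches on a small fixture", {
  # 4 points with known pairwise dissimilarities
  w <- matrix(c(1, .9, .2, .1,
                .9, 1, .3, .2,
                .2, .3, 1, .8,
                .1, .2, .8, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- clusterTOM(w)
  # d(a,b)=.1, d(c,d)=.2, then average linkage between {a,b} and {c,d}:
  # mean(.8,.9,.7,.8)=.8
  expect_equal(sort(hc$height), c(0.1, 0.2, 0.8), tolerance = 1e-12)
})

test_that("block-diagonal TOM is cut into exactly the planted modules", {
  w <- makeBlockTOM(c(30, 25), hi = 1, lo = 0, isolated = 10)
  hc <- clusterTOM(w)
  cols <- cutModules(hc, w, minSize = 20)
  sz <- table(cols)
  expect_equal(unname(sz["turquoise"]), 30L)
  expect_equal(unname(sz["blue"]), 25L)
  expect_equal(unname(sz["grey"]), 10L)
  # zero misassignments: each block maps to one colour
  expect_equal(length(unique(cols[1:30])), 1L)
  expect_equal(length(unique(cols[31:55])), 1L)

  # all-zero off-diagonal: everything grey
  id <- diag(30)
  dimnames(id) <- list(sprintf("g%03d", 1:30), sprintf("g%03d", 1:30))
  expect_true(all(cutModules(clusterTOM(id), id) == "grey"))

  expect_error(cutModules(hc, w, minSize = 1), class = "invalidArgumentError")
})

test_that("module partition always covers all genes and respects minSize", {
  for (seed in c(2, 5, 9)) {
    a <- makeRandomAdjacency(40, seed = seed)
    tom <- topologicalOverlap(a)
    cols <- cutModules(clusterTOM(tom), tom, minSize = 10)
    expect_equal(length(cols), 40L)
    sz <- table(cols[cols != "grey"])
    if (length(sz)) expect_true(min(sz) >= 10)
    expect_equal(sum(cols == "grey") + sum(sz), 40)
  }
})

test_that("colour order follows decreasing size with first-gene tie-break", {
  w <- makeBlockTOM(c(20, 30, 25), hi = 1, lo = 0)
  cols <- cutModules(clusterTOM(w), w, minSize = 20)
  expect_equal(unname(cols[21]), "turquoise")  # size 30 block
  expect_equal(unname(cols[51]), "blue")       # size 25 block
  expect_equal(unname(cols[1]), "brown")       # size 20 block

  # equal sizes: alphabetically first member wins the earlier colour
  w2 <- makeBlockTOM(c(25, 25), hi = 1, lo = 0)
  cols2 <- cutModules(clusterTOM(w2), w2, minSize = 20)
  expect_equal(unname(cols2["g001"]), "turquoise")
  expect_equal(unname(cols2["g026"]), "blue")
})

test_that("within-module connectivity sums match hand computation and conserve", {
  # module of size m with all pairwise a = 1: every member k_in = m - 1
  a <- makeBlockTOM(c(4, 3), hi = 1, lo = 0)   # adjacency-like block matrix
  cols <- setNames(c(rep("turquoise", 4), rep("blue", 3)), rownames(a))
  ct <- withinModuleConnectivity(a, cols)
  expect_equal(ct$k_in[1:4], rep(3, 4))
  expect_equal(ct$k_in[5:7], rep(2, 2 + 1))

  # singleton grey gene -> 0
  a2 <- makeRandomAdjacency(6, seed = 1)
  cols2 <- setNames(c(rep("turquoise", 5), "grey"), rownames(a2))
  ct2 <- withinModuleConnectivity(a2, cols2)
  expect_equal(ct2$k_in[6], 0)

  # hand-summed 6-gene fixture
  expect_equal(ct2$k_in[1], sum(a2[1, 2:5]), tolerance = 1e-12)

  # conservation: sum of k_in over a module equals the module's total
  # off-diagonal adjacency
  mem <- 1:5
  expect_equal(sum(ct2$k_in[mem]),
               sum(a2[mem, mem]) - length(mem), tolerance = 1e-12)

  # ranks are dense within module
  expect_setequal(ct2$rank_in_module[mem], 1:5)
})

test_that("hub selection applies the three rules in order", {
  mkConn <- function(n, kin, col = "turquoise") {
    data.frame(gene_id = sprintf("h%02d", seq_len(n)), module_color = col,
               k_in = kin, rank_in_module = rank(-kin, ties.method = "first"),
               stringsAsFactors = FALSE)
  }
  annAll <- function(n, named = TRUE) {
    data.frame(gene_id = sprintf("h%02d", seq_len(n)),
               named_gene = rep(named, n), stringsAsFactors = FALSE)
  }

  # 30 genes, distinct k_in all below the floor, all named -> exactly
  # ceil(0.1 * 30) top genes
  conn <- mkConn(30, seq(7.5, by = -0.2, length.out = 30))
  hubs <- selectHubs(conn, annAll(30))
  expect_equal(nrow(hubs), 3)
  expect_equal(hubs$gene_id, c("h01", "h02", "h03"))
  expect_true(all(hubs$reason == "top-fraction"))

  # a 4th gene above the k.in floor is appended with reason kin-floor
  kin <- c(30, 25, 20, 8.5, rep(2, 26))
  hubs2 <- selectHubs(mkConn(30, kin), annAll(30))
  expect_equal(nrow(hubs2), 4)
  expect_equal(hubs2$reason, c(rep("top-fraction", 3), "kin-floor"))

  # module of 20 whose top 2 are ESTs: padding walks down until 2 named
  conn3 <- mkConn(20, seq(7.5, by = -0.2, length.out = 20))
  ann3 <- annAll(20)
  ann3$named_gene[1:2] <- FALSE
  hubs3 <- selectHubs(conn3, ann3)
  expect_equal(nrow(hubs3), 4)
  expect_equal(sum(hubs3$named_gene), 2)
  expect_equal(hubs3$reason[3:4], rep("named-padding", 2))

  # missing annotation -> unnamed with warning
  expect_warning(selectHubs(mkConn(20, seq(7.5, by = -0.2, length.out = 20)),
                            annAll(10)),
                 "missing annotation")

  # deterministic and idempotent
  expect_identical(selectHubs(conn, annAll(30)), selectHubs(conn, annAll(30)))
})

test_that("detectModules recovers planted structure on synthetic data", {
  d <- paperDesign()
  se <- simulateExpression(d, nGenes = 150, moduleSizes = c(50, 30),
                           moduleSignalSd = 20, noiseSd = 10, deEffects = NA,
                           outlier = FALSE, seed = 13)
  cc <- correlationMatrix(se)
  net <- powerAdjacency(cc, 6)
  ms <- detectModules(topologicalOverlap(net), net)
  truth <- simulationTruth(se)$module_label
  ari <- mclust::adjustedRandIndex(truth, moduleColors(ms)[names(truth)])
  expect_gte(ari, 0.9)
  # partition accounting
  expect_equal(sum(moduleSizes(ms)) + sum(moduleColors(ms) == "grey"), 150)
})
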