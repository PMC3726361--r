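# Shared fixtures, built in code.

# Small expression matrix with named dimnames.
makeExprMatrix <- function(nGenes = 20, nSamples = 6, seed = 1, sd = 1,
                           baseline = 100) {
  withr::with_seed(seed, {
    m <- matrix(baseline + rnorm(nGenes * nSamples, sd = sd), nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    m
  })
}

# Random symmetric adjacency with unit diagonal, weights in [0, 1].
makeRandomAdjacency <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(sprintf("g%03d", seq_len(n)),
                        sprintf("g%03d", seq_len(n)))
    a
  })
}

# Brute-force triple-loop topological overlap: the independent oracle.
bruteForceTOM <- function(a) {
  n <- nrow(a)
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  w <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a0[i, u] * a0[u, j]
      }
      denom <- min(k[i], k[j]) + 1 - a0[i, j]
      w[i, j] <- if (denom <= 0) 0 else (l + a0[i, j]) / denom
    }
  }
  dimnames(w) <- dimnames(a)
  w
}

# Block-diagonal TOM: within-block overlap `hi`, between-block `lo`.
makeBlockTOM <- function(blockSizes, hi = 1, lo = 0, isolated = 0) {
  n <- sum(blockSizes) + isolated
  w <- matrix(lo, n, n)
  at <- 0
  for (b in blockSizes) {
    idx <- at + seq_len(b)
    w[idx, idx] <- hi
    at <- at + b
  }
  diag(w) <- 1
  dimnames(w) <- list(sprintf("g%03d", seq_len(n)), sprintf("g%03d", seq_len(n)))
  w
}

# Design used throughout: the 7-treatment, 3-replicate + 7-control layout.
paperDesign <- function() simulateDesign()
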