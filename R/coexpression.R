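# Weighted co-expression network construction: Pearson correlations, power
# adjacency, connectivity, the scale-free fit index used to select the soft
# threshold, and the topological overlap matrix.

#' Pearson correlation matrix across samples
#'
#' Correlates every gene pair across all retained samples. Constant genes
#' yield correlation 0 (with a warning) rather than NaN; the diagonal is 1.
#'
#' @param x expression matrix or SummarizedExperiment (>= 3 samples).
#' @param genes optional subset of gene ids.
#' @return symmetric correlation matrix.
#' @export
correlationMatrix <- function(x, genes = NULL) {
  m <- .exprMatrix(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) {
      .keyErr(sprintf("gene(s) not in matrix: %s%s",
                      paste(utils::head(miss, 3), collapse = ", "),
                      if (length(miss) > 3) ", ..." else ""))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 3) .invalidArg("correlation needs at least 3 samples")
  const <- .rowVars(m) == 0
  cc <- suppressWarnings(stats::cor(t(m)))
  if (any(const)) {
    warning(sprintf("%d constant gene(s): correlations set to 0", sum(const)))
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Soft-threshold power adjacency
#'
#' Converts a correlation matrix into a weighted network by the power
#' function \eqn{a_{ij} = |cor_{ij}|^\beta} (unsigned mode). The diagonal is
#' stored as 1 but excluded from all connectivity sums.
#'
#' @param corr symmetric correlation matrix in \[-1, 1\].
#' @param beta positive integer power (the scan domain is integers; see
#'   [pickBeta()]).
#' @param mode only `"unsigned"` is implemented.
#' @param scan optional beta-scan table to carry along (from [pickBeta()]).
#' @return a [CoexpressionNetwork-class].
#' @examples
#' cc <- matrix(c(1, .8, .8, 1), 2, 2, dimnames = list(c("a","b"), c("a","b")))
#' adjacencyMatrix(powerAdjacency(cc, 7))["a", "b"]   # 0.8^7
#' @export
powerAdjacency <- function(corr, beta, mode = "unsigned", scan = NULL) {
  .checkSquareSym(corr, "correlation matrix")
  if (length(beta) != 1L || !is.finite(beta) || beta < 1 || beta != round(beta)) {
    .invalidArg("beta must be a single integer >= 1")
  }
  if (max(abs(corr)) > 1 + 1e-8) .invalidArg("correlations must lie in [-1, 1]")
  mode <- match.arg(mode, "unsigned")
  a <- abs(corr)^beta
  a[a > 1] <- 1
  diag(a) <- 1
  if (is.null(dimnames(a)) || is.null(rownames(a))) {
    dimnames(a) <- list(paste0("g", seq_len(nrow(a))),
                        paste0("g", seq_len(nrow(a))))
  }
  methods::new("CoexpressionNetwork", adjacency = a,
               beta = as.integer(beta), mode = mode,
               scan = if (is.null(scan)) data.frame() else scan)
}

#' @rdname connectivity
#' @export
setMethod("connectivity", "CoexpressionNetwork", function(x) {
  connectivity(x@adjacency)
})

#' @rdname connectivity
#' @export
setMethod("connectivity", "matrix", function(x) {
  .checkSquareSym(x, "adjacency matrix")
  rowSums(x) - diag(x)
})

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `nBins` equal-width bins and regresses
#' log10 of the bin frequency p(k) on log10 of the bin's mean connectivity
#' (plain model), and additionally on k itself (truncated model,
#' `log10 p(k) ~ log10 k + k`). A perfectly scale-free network has plain
#' R-squared 1; the slope estimates the power-law exponent of p(k) ~ k^slope.
#'
#' @param k numeric vector of connectivities (non-positive values are
#'   excluded from the log-log fit).
#' @param nBins number of equal-width bins (default 10); empty bins are
#'   dropped.
#' @return list of class `ScaleFreeFit` with elements `k_bins` (mean k per
#'   occupied bin), `p_k`, `slope`, `r2_plain`, `r2_truncated` (NA when
#'   fewer than 3 occupied bins).
#' @export
scaleFreeFit <- function(k, nBins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 2 || min(k) == max(k)) {
    .fitErr("scale-free fit undefined: fewer than 2 occupied connectivity bins")
  }
  breaks <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  cnt <- table(bin)
  occ <- cnt > 0
  if (sum(occ) < 2) {
    .fitErr("scale-free fit undefined: fewer than 2 occupied connectivity bins")
  }
  kBin <- tapply(k, bin, mean)[occ]
  pK <- as.numeric(cnt[occ]) / length(k)
  lx <- log10(kBin)
  ly <- log10(pK)
  # a perfect fit is a legitimate input (exactly affine log-log data), so
  # summary.lm's perfect-fit warning is suppressed
  plain <- stats::lm(ly ~ lx)
  r2Plain <- suppressWarnings(summary(plain)$r.squared)
  r2t <- NA_real_
  if (sum(occ) >= 3) {
    trunc <- stats::lm(ly ~ lx + kBin)
    r2t <- suppressWarnings(summary(trunc)$r.squared)
  }
  structure(list(k_bins = unname(kBin), p_k = pK,
                 slope = unname(stats::coef(plain)[2]),
                 r2_plain = r2Plain,
                 r2_truncated = r2t),
            class = "ScaleFreeFit")
}

#' Scan soft-threshold powers and pick the smallest scale-free one
#'
#' For each integer power in `betas` (ascending), builds the unsigned power
#' adjacency, computes the connectivity distribution and its scale-free fit,
#' and returns the smallest power whose truncated fit R-squared exceeds
#' `r2Min`. If no power qualifies, the power maximising the truncated
#' R-squared is returned with `qualified = FALSE` and a warning.
#'
#' @param corr symmetric correlation matrix (or expression input accepted by
#'   [correlationMatrix()] when `fromExpression = TRUE`).
#' @param betas integer powers to scan (default 1:20).
#' @param r2Min scale-free fit threshold (default 0.75).
#' @param nBins bins for [scaleFreeFit()].
#' @param fromExpression treat `corr` as expression input and correlate it
#'   first.
#' @return list with `beta` (selected power), `qualified` (logical), and
#'   `scan` (data.frame beta/slope/r2_plain/r2_truncated).
#' @export
pickBeta <- function(corr, betas = 1:20, r2Min = 0.75, nBins = 10,
                     fromExpression = FALSE) {
  if (!length(betas)) .invalidArg("empty beta range")
  if (any(betas != round(betas)) || any(betas < 1)) {
    .invalidArg("betas must be positive integers")
  }
  if (fromExpression) corr <- correlationMatrix(corr)
  .checkSquareSym(corr, "correlation matrix")
  betas <- sort(unique(as.integer(betas)))
  ac <- abs(corr)
  rows <- lapply(betas, function(b) {
    a <- ac^b
    diag(a) <- 0
    k <- rowSums(a)
    fit <- tryCatch(scaleFreeFit(k, nBins), undefinedFitError = function(e) NULL)
    if (is.null(fit)) {
      data.frame(beta = b, slope = NA_real_, r2_plain = NA_real_,
                 r2_truncated = NA_real_)
    } else {
      data.frame(beta = b, slope = fit$slope, r2_plain = fit$r2_plain,
                 r2_truncated = fit$r2_truncated)
    }
  })
  scan <- do.call(rbind, rows)
  sel <- selectBeta(scan, r2Min)
  c(sel, list(scan = scan))
}

#' Select the soft threshold from a beta-scan table
#'
#' Returns the smallest beta whose truncated R-squared strictly exceeds
#' `r2Min`; falls back (with a warning) to the beta maximising the truncated
#' R-squared when none qualifies.
#'
#' @param scan data.frame with columns `beta` and `r2_truncated`.
#' @param r2Min qualification threshold (default 0.75).
#' @return list with `beta` and `qualified`.
#' @export
selectBeta <- function(scan, r2Min = 0.75) {
  if (!nrow(scan)) .invalidArg("empty beta scan")
  r2 <- scan$r2_truncated
  ok <- which(!is.na(r2) & r2 > r2Min)
  if (length(ok)) {
    return(list(beta = as.integer(scan$beta[min(ok)]), qualified = TRUE))
  }
  if (all(is.na(r2))) .fitErr("no beta produced a defined scale-free fit")
  warning(sprintf("no beta reached truncated R^2 > %.2f; using argmax", r2Min))
  list(beta = as.integer(scan$beta[which.max(r2)]), qualified = FALSE)
}

#' Topological overlap matrix
#'
#' Transforms an adjacency matrix into the topological overlap matrix
#' \deqn{\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and \eqn{\omega_{ii} =
#' 1}. The overlap reflects both direct interaction and shared neighbours.
#' Fully isolated pairs (zero denominator) get \eqn{\omega = 0}.
#'
#' @param x a [CoexpressionNetwork-class] or symmetric adjacency matrix with
#'   weights in \[0, 1\].
#' @return a [TOMatrix-class].
#' @export
topologicalOverlap <- function(x) {
  a <- if (methods::is(x, "CoexpressionNetwork")) x@adjacency else x
  .checkSquareSym(a, "adjacency matrix")
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12) {
    .invalidArg("adjacency weights must lie in [0, 1]")
  }
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0           # l_ij = sum_u a_iu a_uj, u != i,j by zero diagonal
  k <- rowSums(a0)
  minK <- outer(k, k, pmin)
  denom <- minK + 1 - a0
  w <- (l + a0) / denom
  w[denom <= 0] <- 0
  diag(w) <- 1
  w[w > 1] <- 1
  w[w < 0] <- 0
  w <- (w + t(w)) / 2
  if (is.null(rownames(w))) {
    dimnames(w) <- list(paste0("g", seq_len(nrow(w))),
                        paste0("g", seq_len(nrow(w))))
  }
  methods::new("TOMatrix", omega = w)
}
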