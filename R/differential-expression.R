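# Array-level QC and per-treatment signature-list derivation under a
# three-criterion filter: fold change of group means, t-test p-value against
# control, and absolute difference of group means.

#' Default differential-expression criteria
#'
#' Fold change of group means >= 1.2 or <= 0.83, t-test p <= 0.05 against
#' control, and absolute difference of group means >= 10 on the linear
#' intensity scale. All boundaries are inclusive. The deliberately loose
#' fold-change cutoff keeps borderline genes in play for the downstream
#' network stages, which act as a further filter.
#'
#' @param fcUp up-regulation fold-change threshold (default 1.2).
#' @param fcDown down-regulation threshold (default 0.83).
#' @param pMax maximum t-test p-value (default 0.05).
#' @param minAbsDiff minimum absolute difference of group means (default 10).
#' @return list of class `DECriteria`.
#' @export
deCriteria <- function(fcUp = 1.2, fcDown = 0.83, pMax = 0.05, minAbsDiff = 10) {
  if (!(fcUp > 1 && fcDown < 1 && fcDown > 0)) {
    .invalidArg("need fcUp > 1 > fcDown > 0")
  }
  if (pMax <= 0 || pMax >= 1) .invalidArg("pMax must be in (0, 1)")
  if (minAbsDiff < 0) .invalidArg("minAbsDiff must be >= 0")
  structure(list(fcUp = fcUp, fcDown = fcDown, pMax = pMax,
                 minAbsDiff = minAbsDiff), class = "DECriteria")
}

#' Flag outlier arrays by Kolmogorov-Smirnov distance
#'
#' For each sample, computes the two-sample KS distance between its
#' intensity distribution and the pooled distribution of all other samples;
#' samples with distance above `threshold` are flagged. A globally distorted
#' chip (e.g. a scaling artefact) stands out sharply on this statistic.
#'
#' @param x expression matrix or SummarizedExperiment (>= 3 samples).
#' @param threshold KS distance above which a sample is flagged
#'   (default 0.25; the statistic is bounded by 1).
#' @return data.frame with columns `sample_id`, `ks_distance`, `flagged`.
#' @examples
#' m <- matrix(rep(1:50, 4), 50, 4, dimnames = list(paste0("g", 1:50),
#'             paste0("s", 1:4)))
#' flagOutlierArrays(m)   # identical columns: nothing flagged
#' @export
flagOutlierArrays <- function(x, threshold = 0.25) {
  m <- .exprMatrix(x)
  if (ncol(m) < 3) .invalidArg("outlier QC needs at least 3 samples")
  d <- vapply(seq_len(ncol(m)), function(j) {
    ks <- suppressWarnings(stats::ks.test(m[, j], as.vector(m[, -j])))
    unname(ks$statistic)
  }, numeric(1))
  data.frame(sample_id = colnames(m), ks_distance = d,
             flagged = d > threshold, stringsAsFactors = FALSE)
}

#' Remove a batch effect by mean-centering within batches
#'
#' Per gene and batch, subtracts the batch mean and adds back the gene's
#' grand mean, so per-gene grand means are unchanged. This approximates
#' using the processing batch as a blocking factor before testing.
#'
#' @param x expression matrix or SummarizedExperiment.
#' @param design design data.frame (taken from colData when `x` is a
#'   SummarizedExperiment). Every batch must have >= 2 samples.
#' @return object of the same type as `x` with centered intensities.
#' @export
batchCenter <- function(x, design = NULL) {
  m <- .exprMatrix(x)
  design <- .designOf(x, design)
  design <- design[match(colnames(m), design$sample_id), ]
  if (anyNA(design$sample_id)) .keyErr("samples missing from design")
  tab <- table(design$batch)
  if (any(tab < 2)) .invalidArg("every batch must contain at least 2 samples")
  grand <- rowMeans(m)
  out <- m
  for (b in names(tab)) {
    j <- which(as.character(design$batch) == b)
    out[, j] <- m[, j] - rowMeans(m[, j, drop = FALSE]) + grand
  }
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, 1L) <- out
    x
  } else {
    out
  }
}

# Row-wise two-sample t test (Welch by default, pooled-variance optional).
# Zero variance in both groups gives t = 0/0 for equal means -> p = 1;
# perfect separation (zero variance, different means) gives p = 0.
.rowTTest <- function(mT, mC, vT, vC, nT, nC, varEqual = FALSE) {
  if (varEqual) {
    sp2 <- ((nT - 1) * vT + (nC - 1) * vC) / (nT + nC - 2)
    se <- sqrt(sp2 * (1 / nT + 1 / nC))
    df <- rep(nT + nC - 2, length(mT))
  } else {
    a <- vT / nT
    b <- vC / nC
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (nT - 1) + b^2 / (nC - 1))
  }
  t <- (mT - mC) / se
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0 & mT == mC] <- 1
  p[se == 0 & mT != mC] <- 0
  list(t = t, p = p, df = df)
}

#' Per-treatment differential-expression signature list
#'
#' For each gene, computes the control and treated group means, the fold
#' change as their ratio, a two-sided two-sample t-test p-value and the
#' absolute difference of means, then applies the three criteria in
#' `criteria` (boundary values pass). Genes with zero control mean report an
#' infinite fold change rather than being dropped.
#'
#' @param x expression matrix or SummarizedExperiment.
#' @param design design data.frame (from colData when omitted).
#' @param treatment treatment label to contrast against `"control"`.
#' @param criteria a [deCriteria()] list.
#' @param varEqual use the pooled-variance (Student) t test instead of
#'   Welch's (default FALSE).
#' @return data.frame with one row per gene: `gene_id`, `mean_control`,
#'   `mean_treated`, `fold_change`, `p_value`, `abs_diff`, `direction`
#'   (up/down), `passes`; the treatment name is kept in
#'   `attr(., "treatment")`.
#' @examples
#' d <- simulateDesign(2, 3, 4, 2)
#' se <- simulateExpression(d, nGenes = 100, moduleSizes = integer(0),
#'                          outlier = FALSE, seed = 3)
#' sig <- signatureList(se, treatment = "CTGF")
#' sum(sig$passes)
#' @export
signatureList <- function(x, design = NULL, treatment, criteria = deCriteria(),
                          varEqual = FALSE) {
  m <- .exprMatrix(x)
  design <- .designOf(x, design)
  design <- design[design$sample_id %in% colnames(m), ]
  if (!treatment %in% design$treatment) {
    .keyErr(sprintf("treatment '%s' not present in design", treatment))
  }
  trtIdx <- match(design$sample_id[design$treatment == treatment], colnames(m))
  ctlIdx <- match(design$sample_id[design$treatment == "control"], colnames(m))
  if (length(trtIdx) < 2) .invalidArg("need >= 2 treated replicates")
  if (length(ctlIdx) < 2) .invalidArg("need >= 2 control samples")

  mT <- rowMeans(m[, trtIdx, drop = FALSE])
  mC <- rowMeans(m[, ctlIdx, drop = FALSE])
  vT <- .rowVars(m[, trtIdx, drop = FALSE])
  vC <- .rowVars(m[, ctlIdx, drop = FALSE])
  tt <- .rowTTest(mT, mC, vT, vC, length(trtIdx), length(ctlIdx), varEqual)

  fc <- mT / mC
  fc[mC == 0 & mT > 0] <- Inf
  fc[mC == 0 & mT == 0] <- 1
  absDiff <- abs(mT - mC)
  passes <- (fc >= criteria$fcUp | fc <= criteria$fcDown) &
    tt$p <= criteria$pMax & absDiff >= criteria$minAbsDiff

  out <- data.frame(
    gene_id = rownames(m),
    mean_control = mC, mean_treated = mT,
    fold_change = fc, p_value = tt$p, abs_diff = absDiff,
    direction = ifelse(fc > 1, "up", "down"),
    passes = passes,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "treatment") <- treatment
  attr(out, "criteria") <- criteria
  out
}

#' Signature lists for all treatments in a design
#'
#' @inheritParams signatureList
#' @return named list of signature data.frames, one per non-control
#'   treatment.
#' @export
deSignatures <- function(x, design = NULL, criteria = deCriteria(),
                         varEqual = FALSE) {
  design <- .designOf(x, design)
  trts <- setdiff(unique(design$treatment), "control")
  stats::setNames(
    lapply(trts, function(t) signatureList(x, design, t, criteria, varEqual)),
    trts)
}

#' Cross-treatment union of signature lists
#'
#' One row per gene passing the filter in at least one treatment, with a
#' per-treatment direction column (`up`/`down`/empty) and the number of
#' treatments in which the gene passes.
#'
#' @param signatures named list of signature data.frames from
#'   [signatureList()] / [deSignatures()].
#' @return data.frame with columns `gene_id`, one direction column per
#'   treatment, and `n_treatments`.
#' @export
unionSignatures <- function(signatures) {
  if (!length(signatures)) .invalidArg("need at least one signature list")
  if (is.null(names(signatures))) {
    names(signatures) <- vapply(signatures, attr, character(1), "treatment")
  }
  genes <- sort(unique(unlist(lapply(signatures, function(s) {
    s$gene_id[s$passes]
  }))))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (t in names(signatures)) {
    s <- signatures[[t]]
    dir <- stats::setNames(ifelse(s$passes, s$direction, ""), s$gene_id)
    out[[t]] <- unname(dir[genes])
    out[[t]][is.na(out[[t]])] <- ""
  }
  out$n_treatments <- rowSums(out[, names(signatures), drop = FALSE] != "")
  out
}
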