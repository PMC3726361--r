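# Internal helpers shared across the package.

# Classed errors so callers can condition on failure modes.
.anErr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "assemblyNetError", "error", "condition")))
}

.invalidArg <- function(msg) .anErr(msg, "invalidArgumentError")
.keyErr     <- function(msg) .anErr(msg, "keyError")
.parseErr   <- function(msg) .anErr(msg, "parseError")
.ioErr      <- function(msg) .anErr(msg, "ioError")
.fitErr     <- function(msg) .anErr(msg, "undefinedFitError")

# All randomness is drawn under an explicit seed; global RNG state untouched.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .invalidArg("'seed' must be a single integer")
  }
  withr::with_seed(as.integer(seed), code)
}

# Extract an intensity matrix (genes x samples) and a design data.frame from
# either a SummarizedExperiment or a plain matrix + design pair.
.exprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, 1L)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    .invalidArg("expression input must be a SummarizedExperiment or a matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    .invalidArg("expression matrix must have gene row names and sample column names")
  }
  if (anyNA(m)) .invalidArg("expression matrix contains missing values")
  m
}

.designOf <- function(x, design = NULL) {
  if (is.null(design) && methods::is(x, "SummarizedExperiment")) {
    design <- as.data.frame(SummarizedExperiment::colData(x))
    if (!"sample_id" %in% names(design)) design$sample_id <- colnames(x)
  }
  if (is.null(design)) .invalidArg("a design table is required")
  need <- c("sample_id", "treatment", "batch")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    .parseErr(sprintf("design table is missing column(s): %s",
                      paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) .invalidArg("design sample_ids must be unique")
  design[, need]
}

.checkSquareSym <- function(m, what, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) .invalidArg(sprintf("%s must be square", what))
  if (max(abs(m - t(m))) > tol) .invalidArg(sprintf("%s must be symmetric", what))
  invisible(m)
}

# Row-wise variance without forming large intermediates gene-by-gene.
.rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Deterministic TSV writer used for every tabular output (stable checksums).
.writeTSV <- function(df, path, rowNames = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE, eol = "\n")
  invisible(path)
}

.readTSV <- function(path, ...) {
  if (!file.exists(path)) .ioErr(sprintf("file not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

# Standard module colour sequence (largest module first), grey = unassigned.
.MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

.moduleColorName <- function(i) {
  ifelse(i <= length(.MODULE_COLORS), .MODULE_COLORS[i], paste0("module", i))
}
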