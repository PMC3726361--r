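# Readers and writers for the plain-text interchange formats: expression and
# design TSV, gene annotation TSV, GMT gene-set collections, SIF-like edge
# lists, Newick dendrograms and GraphML graphs.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path TSV file path.
#' @param design optional design data.frame; when given, the result is a
#'   SummarizedExperiment with the design as colData, otherwise a matrix.
#' @return matrix or SummarizedExperiment (assay `intensity`).
#' @export
readExpression <- function(path, design = NULL) {
  df <- .readTSV(path)
  if (ncol(df) < 2) .parseErr("expression TSV needs a gene id column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) .parseErr("expression values must be numeric")
  if (anyNA(m)) .parseErr("expression matrix contains missing values")
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) .parseErr("duplicate gene ids in expression TSV")
  if (is.null(design)) return(m)
  design <- .designOf(NULL, design)
  if (!all(colnames(m) %in% design$sample_id)) {
    .invalidArg("expression sample ids must all appear in the design")
  }
  design <- design[match(colnames(m), design$sample_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
}

#' Write an expression matrix (or SummarizedExperiment assay) to TSV
#'
#' @param x matrix or SummarizedExperiment.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExpression <- function(x, path) {
  m <- .exprMatrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Requires columns `sample_id`, `treatment`, `batch`. Every treatment label
#' must have at least two samples.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readDesign <- function(path) {
  design <- .designOf(NULL, .readTSV(path))
  design$sample_id <- as.character(design$sample_id)
  design$treatment <- as.character(design$treatment)
  if (!is.numeric(design$batch)) .parseErr("design column 'batch' must be numeric")
  tab <- table(design$treatment)
  if (any(tab < 2)) {
    .invalidArg(sprintf("treatment label(s) with fewer than 2 samples: %s",
                        paste(names(tab)[tab < 2], collapse = ", ")))
  }
  design
}

#' Read a gene annotation table from TSV
#'
#' Requires columns `gene_id`, `symbol`, `named_gene` (logical: symbol vs
#' EST); extra columns are kept.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readAnnotation <- function(path) {
  ann <- .readTSV(path)
  need <- c("gene_id", "symbol", "named_gene")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    .parseErr(sprintf("annotation is missing column(s): %s",
                      paste(miss, collapse = ", ")))
  }
  ann$named_gene <- as.logical(ann$named_gene)
  ann
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `descriptions` attribute.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) .ioErr(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      .parseErr(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    nm <- fields[1]
    if (nm %in% names(sets)) .parseErr(sprintf("duplicate set name '%s'", nm))
    sets[[nm]] <- unique(fields[-(1:2)])
    desc[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (defaults to set names).
#' @return the path, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    .invalidArg("gene sets must be named")
  }
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` object (e.g. from [clusterTOM()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDendrogramNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a labelled overlap matrix to TSV
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeOverlapMatrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
  invisible(path)
}
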