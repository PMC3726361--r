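#' @import methods
NULL

#' Weighted co-expression network
#'
#' Holds the soft-thresholded adjacency matrix \eqn{a_{ij} = |cor_{ij}|^\beta}
#' together with the power \eqn{\beta} used and, when the power was chosen by
#' a scale-free scan, the full scan table.
#'
#' @slot adjacency symmetric numeric matrix of connection strengths in
#'   \[0, 1\], diagonal stored as 1 (excluded from connectivity sums).
#' @slot beta integer soft-threshold power.
#' @slot mode character, currently \code{"unsigned"}.
#' @slot scan data.frame with columns \code{beta}, \code{slope},
#'   \code{r2_plain}, \code{r2_truncated} (may be empty).
#'
#' @seealso [powerAdjacency()], [pickBeta()], [topologicalOverlap()]
#' @export
setClass("CoexpressionNetwork",
  representation(adjacency = "matrix", beta = "integer", mode = "character",
                 scan = "data.frame"))

setValidity("CoexpressionNetwork", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    return("adjacency needs identical row and column gene names")
  if (max(abs(a - t(a))) > 1e-8) return("adjacency must be symmetric")
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
    return("adjacency weights must lie in [0, 1]")
  if (any(abs(diag(a) - 1) > 1e-12)) return("adjacency diagonal must be 1")
  if (length(object@beta) != 1L || object@beta < 1L)
    return("beta must be a single integer >= 1")
  if (!object@mode %in% "unsigned") return("mode must be 'unsigned'")
  TRUE
})

#' Topological overlap matrix
#'
#' Pairwise similarity \eqn{\omega_{ij}} combining direct adjacency and
#' shared-neighbour adjacency, bounded in \[0, 1\] with unit diagonal.
#'
#' @slot omega symmetric numeric matrix in \[0, 1\], diagonal 1.
#' @seealso [topologicalOverlap()], [clusterTOM()]
#' @export
setClass("TOMatrix", representation(omega = "matrix"))

setValidity("TOMatrix", function(object) {
  w <- object@omega
  if (nrow(w) != ncol(w)) return("omega must be square")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    return("omega needs identical row and column gene names")
  if (max(abs(w - t(w))) > 1e-8) return("omega must be symmetric")
  if (min(w) < -1e-12 || max(w) > 1 + 1e-12) return("omega must lie in [0, 1]")
  if (any(abs(diag(w) - 1) > 1e-12)) return("omega diagonal must be 1")
  TRUE
})

#' Module assignment with intramodular connectivity
#'
#' Result of cutting the topological-overlap dendrogram: a colour per gene
#' (grey = unassigned), the dendrogram itself, and the within-module
#' connectivity (k.in) table.
#'
#' @slot colors named character vector, gene id -> module colour.
#' @slot dendrogram the \code{hclust} object the cut was made on.
#' @slot connectivity data.frame with columns \code{gene_id},
#'   \code{module_color}, \code{k_in}, \code{rank_in_module}.
#' @slot params list of the cut parameters used.
#' @seealso [detectModules()], [cutModules()], [selectHubs()]
#' @export
setClass("ModuleSet",
  representation(colors = "character", dendrogram = "ANY",
                 connectivity = "data.frame", params = "list"))

setValidity("ModuleSet", function(object) {
  if (is.null(names(object@colors))) return("colors must be named by gene id")
  minSize <- object@params$minSize
  if (!is.null(minSize)) {
    sz <- table(object@colors[object@colors != "grey"])
    if (length(sz) && min(sz) < minSize)
      return("a non-grey module is smaller than minSize")
  }
  TRUE
})

#' Gene-gene interaction graph
#'
#' A literature-style interaction network loaded from a SIF-like edge list.
#' Relation types follow the usual curated-database vocabulary (regulation,
#' expression, promoter-binding, protein-modification, binding); binding is
#' stored undirected, the rest directed.
#'
#' @slot edges data.frame with columns \code{source}, \code{relation},
#'   \code{target}, \code{directed}.
#' @slot nodes character vector of node gene ids.
#' @seealso [readEdgeList()], [inducedSubnetwork()], [rankByNeighbors()]
#' @export
setClass("InteractionGraph",
  representation(edges = "data.frame", nodes = "character"))

setValidity("InteractionGraph", function(object) {
  e <- object@edges
  need <- c("source", "relation", "target", "directed")
  if (!all(need %in% names(e))) return("edges must have source/relation/target/directed")
  if (nrow(e) && any(e$source == e$target)) return("self-loops are not allowed")
  if (nrow(e) && !all(c(e$source, e$target) %in% object@nodes))
    return("all edge endpoints must be listed in nodes")
  TRUE
})
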