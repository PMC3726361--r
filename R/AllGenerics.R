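#' @rdname CoexpressionNetwork-class
#' @param object,x an object.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("betaScan", function(x) standardGeneric("betaScan"))

#' Per-gene whole-network connectivity
#'
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}: the sum of a gene's connection
#' strengths to every other gene, diagonal excluded.
#'
#' @param x a [CoexpressionNetwork-class] or a symmetric adjacency matrix.
#' @return named numeric vector of connectivities.
#' @examples
#' a <- matrix(c(1, .5, .5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' connectivity(a)
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))

#' @rdname TOMatrix-class
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleColors", function(x) standardGeneric("moduleColors"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname ModuleSet-class
#' @export
setGeneric("connectivityTable", function(x) standardGeneric("connectivityTable"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

# ---- accessors / show ------------------------------------------------------

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("softPower", "CoexpressionNetwork", function(x) x@beta)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("betaScan", "CoexpressionNetwork", function(x) x@scan)

#' @rdname TOMatrix-class
#' @export
setMethod("tomMatrix", "TOMatrix", function(x) x@omega)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleColors", "ModuleSet", function(x) x@colors)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleSizes", "ModuleSet", function(x) {
  cols <- x@colors[x@colors != "grey"]
  if (!length(cols)) return(integer(0))
  sz <- table(cols)
  ord <- order(-as.integer(sz), match(names(sz), .MODULE_COLORS))
  stats::setNames(as.integer(sz)[ord], names(sz)[ord])
})

#' @rdname ModuleSet-class
#' @export
setMethod("connectivityTable", "ModuleSet", function(x) x@connectivity)

#' @rdname InteractionGraph-class
#' @export
setMethod("edgeTable", "InteractionGraph", function(x) x@edges)

#' @rdname InteractionGraph-class
#' @export
setMethod("graphNodes", "InteractionGraph", function(x) x@nodes)

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf("CoexpressionNetwork: %d genes, beta = %d (%s)\n",
              nrow(object@adjacency), object@beta, object@mode))
  if (nrow(object@scan))
    cat(sprintf("  beta scan: %d powers evaluated\n", nrow(object@scan)))
})

setMethod("show", "TOMatrix", function(object) {
  cat(sprintf("TOMatrix: %d genes, mean off-diagonal overlap %.4f\n",
              nrow(object@omega),
              mean(object@omega[upper.tri(object@omega)])))
})

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat(sprintf("ModuleSet: %d genes, %d modules (grey: %d)\n",
              length(object@colors), length(sz),
              sum(object@colors == "grey")))
  if (length(sz)) {
    cat("  ", paste(sprintf("%s=%d", names(sz), sz), collapse = ", "), "\n")
  }
})

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph: %d nodes, %d edges (%d directed)\n",
              length(object@nodes), nrow(object@edges),
              sum(object@edges$directed)))
})
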