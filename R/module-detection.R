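# Module detection: average-linkage clustering on topological-overlap
# dissimilarity, a static branch cut with a minimum module size and a
# low-overlap demotion step, within-module connectivity (k.in), and the
# hub-selection rules (top fraction, k.in floor, named-gene padding).

#' Average-linkage clustering on topological overlap
#'
#' Clusters genes on the dissimilarity \eqn{d = 1 - \omega} with
#' average-linkage agglomeration. Deterministic for a given input ordering.
#'
#' @param tom a [TOMatrix-class] or symmetric matrix in \[0, 1\].
#' @return an `hclust` object.
#' @export
clusterTOM <- function(tom) {
  w <- if (methods::is(tom, "TOMatrix")) tom@omega else tom
  .checkSquareSym(w, "topological overlap matrix")
  if (nrow(w) < 2) .invalidArg("clustering needs at least 2 genes")
  hc <- stats::hclust(stats::as.dist(1 - w), method = "average")
  # guard against sub-epsilon height inversions from floating-point noise
  hc$height <- cummax(hc$height)
  hc
}

#' Cut a dendrogram into colour-named modules
#'
#' Cuts the tree at `cutHeightFrac` times the maximum merge height; branches
#' with at least `minSize` leaves become modules and all other genes are
#' assigned to grey. Within each candidate module, loosely attached genes —
#' those whose mean overlap with their co-members falls below half the
#' module's median mean overlap — are demoted to grey (a light stability
#' step that strips background genes chained onto a branch without touching
#' exact block structure); demotion never shrinks a module below `minSize`
#' (it is skipped for that module instead).
#' Colours are assigned in a fixed order by decreasing module size
#' (turquoise, blue, brown, ...), with equal sizes broken by the
#' alphabetically first member gene id.
#'
#' @param dendro `hclust` from [clusterTOM()].
#' @param tom the [TOMatrix-class] the dendrogram was built from.
#' @param minSize smallest allowed module (default 20).
#' @param cutHeightFrac cut height as a fraction of the maximum merge height
#'   (default 0.99).
#' @return named character vector gene id -> colour (`"grey"` = unassigned).
#' @export
cutModules <- function(dendro, tom, minSize = 20, cutHeightFrac = 0.99) {
  if (minSize < 2) .invalidArg("minSize must be >= 2")
  w <- if (methods::is(tom, "TOMatrix")) tom@omega else tom
  genes <- dendro$labels
  if (is.null(genes)) genes <- rownames(w)
  h <- cutHeightFrac * max(dendro$height)
  grp <- stats::cutree(dendro, h = h)
  colors <- stats::setNames(rep("grey", length(genes)), genes)

  keep <- list()
  for (g in unique(grp)) {
    members <- genes[grp == g]
    if (length(members) < minSize) next
    ww <- w[members, members, drop = FALSE]
    meanOmega <- (rowSums(ww) - diag(ww)) / (length(members) - 1)
    cutoff <- 0.5 * stats::median(meanOmega)
    retained <- members[meanOmega >= cutoff]
    if (length(retained) < minSize) retained <- members
    keep[[length(keep) + 1L]] <- retained
  }
  if (length(keep)) {
    sizes <- lengths(keep)
    firstGene <- vapply(keep, function(g) min(g), character(1))
    ord <- order(-sizes, firstGene)
    for (i in seq_along(ord)) {
      colors[keep[[ord[i]]]] <- .moduleColorName(i)
    }
  }
  colors
}

#' Within-module connectivity (k.in)
#'
#' The k.in of a gene is the sum of its connection strengths with all other
#' genes in the module it belongs to. Grey genes get their k.in over grey
#' co-members (reported, but never used for hub selection).
#'
#' @param adj a [CoexpressionNetwork-class] or adjacency matrix.
#' @param colors named character vector from [cutModules()], covering all
#'   genes in `adj`.
#' @return data.frame with columns `gene_id`, `module_color`, `k_in`,
#'   `rank_in_module` (dense rank by decreasing k.in within module).
#' @export
withinModuleConnectivity <- function(adj, colors) {
  a <- if (methods::is(adj, "CoexpressionNetwork")) adj@adjacency else adj
  .checkSquareSym(a, "adjacency matrix")
  genes <- rownames(a)
  if (!all(genes %in% names(colors))) {
    .keyErr("module assignment does not cover all genes in the adjacency")
  }
  colors <- colors[genes]
  kIn <- numeric(length(genes))
  for (col in unique(colors)) {
    members <- which(colors == col)
    if (length(members) == 1L) { kIn[members] <- 0; next }
    sub <- a[members, members, drop = FALSE]
    kIn[members] <- rowSums(sub) - diag(sub)
  }
  out <- data.frame(gene_id = genes, module_color = unname(colors),
                    k_in = kIn, stringsAsFactors = FALSE)
  out$rank_in_module <- stats::ave(-out$k_in, out$module_color,
                                   FUN = function(v) rank(v, ties.method = "first"))
  out
}

#' Detect modules from a topological overlap matrix
#'
#' Convenience wrapper: clusters, cuts, and computes within-module
#' connectivity, returning a [ModuleSet-class].
#'
#' @inheritParams cutModules
#' @param adj the [CoexpressionNetwork-class] (or adjacency matrix) used for
#'   k.in; pass the network the TOM was derived from.
#' @return a [ModuleSet-class].
#' @export
detectModules <- function(tom, adj, minSize = 20, cutHeightFrac = 0.99) {
  dendro <- clusterTOM(tom)
  colors <- cutModules(dendro, tom, minSize, cutHeightFrac)
  conn <- withinModuleConnectivity(adj, colors)
  methods::new("ModuleSet", colors = colors, dendrogram = dendro,
               connectivity = conn,
               params = list(minSize = minSize, cutHeightFrac = cutHeightFrac))
}

#' Select hub genes per module
#'
#' Per non-grey module: take the top `ceiling(fraction * size)` genes by
#' k.in (ties broken alphabetically by gene id); append any remaining genes
#' with k.in strictly above `kinFloor`; and if fewer named (non-EST) genes
#' than `ceiling(fraction * size)` were selected, keep appending
#' next-highest-k.in genes until that many named genes are included (or the
#' module is exhausted).
#'
#' @param x a [ModuleSet-class] or a connectivity data.frame from
#'   [withinModuleConnectivity()].
#' @param annotation data.frame with `gene_id` and `named_gene`; genes with
#'   missing annotation are treated as unnamed with a warning.
#' @param fraction top fraction per module (default 0.10).
#' @param kinFloor absolute k.in threshold for extra hubs (default 8; this
#'   is an adjacency-sum scale and therefore configurable).
#' @return data.frame with columns `module_color`, `gene_id`, `k_in`,
#'   `named_gene`, `reason` (top-fraction / kin-floor / named-padding),
#'   ordered by module then decreasing k.in.
#' @export
selectHubs <- function(x, annotation, fraction = 0.10, kinFloor = 8) {
  conn <- if (methods::is(x, "ModuleSet")) connectivityTable(x) else x
  mods <- setdiff(unique(conn$module_color), "grey")
  if (!length(mods)) .invalidArg("no non-grey module in the connectivity table")
  named <- stats::setNames(annotation$named_gene, annotation$gene_id)
  out <- list()
  for (col in sort(mods)) {
    tab <- conn[conn$module_color == col, ]
    tab <- tab[order(-tab$k_in, tab$gene_id), ]
    isNamed <- named[tab$gene_id]
    if (anyNA(isNamed)) {
      warning(sprintf("%d gene(s) in module %s missing annotation; treated as unnamed",
                      sum(is.na(isNamed)), col))
      isNamed[is.na(isNamed)] <- FALSE
    }
    nTop <- ceiling(fraction * nrow(tab))
    reason <- rep(NA_character_, nrow(tab))
    reason[seq_len(nTop)] <- "top-fraction"
    extra <- which(is.na(reason) & tab$k_in > kinFloor)
    reason[extra] <- "kin-floor"
    sel <- !is.na(reason)
    while (sum(isNamed[sel]) < nTop && any(!sel)) {
      nxt <- which(!sel)[1]       # table already ordered by k_in
      reason[nxt] <- "named-padding"
      sel[nxt] <- TRUE
    }
    out[[col]] <- data.frame(module_color = col,
                             gene_id = tab$gene_id[sel],
                             k_in = tab$k_in[sel],
                             named_gene = unname(isNamed[sel]),
                             reason = reason[sel],
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
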