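# Operations on user-supplied gene-gene interaction edge lists: loading a
# SIF-like TSV, induced subnetworks, neighbour-connection ranking with
# source/sink roles, and the hub-gene network.

.KNOWN_RELATIONS <- c("regulation", "expression", "promoter-binding",
                      "protein-modification", "binding")
.UNDIRECTED_RELATIONS <- "binding"

# Canonicalize and validate an edge data.frame into an InteractionGraph.
.makeGraph <- function(edges, nodes = NULL) {
  if (!nrow(edges)) {
    return(methods::new("InteractionGraph",
                        edges = data.frame(source = character(0),
                                           relation = character(0),
                                           target = character(0),
                                           directed = logical(0)),
                        nodes = if (is.null(nodes)) character(0) else nodes))
  }
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  edges$directed <- !(edges$relation %in% .UNDIRECTED_RELATIONS)
  flip <- !edges$directed & edges$source > edges$target
  tmp <- edges$source[flip]
  edges$source[flip] <- edges$target[flip]
  edges$target[flip] <- tmp
  edges <- edges[!duplicated(edges[, c("source", "relation", "target")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$relation), ]
  rownames(edges) <- NULL
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  methods::new("InteractionGraph", edges = edges, nodes = nodes)
}

#' Load a gene-gene interaction edge list
#'
#' Reads a SIF-compatible three-column TSV (`source`, `relation`, `target`;
#' a header row matching those names is skipped). Malformed rows are
#' reported with their line numbers and dropped with a warning; duplicate
#' edges are collapsed; self-loops removed; unknown relation types are kept
#' as-is with a warning. Binding edges are stored undirected (once), all
#' other relations directed.
#'
#' @param path TSV/SIF file path.
#' @return an [InteractionGraph-class].
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) .ioErr(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(keep & lengths(fields) != 3L)
  if (length(bad)) {
    warning(sprintf("dropped %d malformed line(s): %s", length(bad),
                    paste(utils::head(bad, 10), collapse = ", ")))
  }
  ok <- which(keep & lengths(fields) == 3L)
  if (!length(ok)) return(.makeGraph(data.frame(source = character(0),
                                                relation = character(0),
                                                target = character(0))))
  m <- do.call(rbind, fields[ok])
  edges <- data.frame(source = m[, 1], relation = m[, 2], target = m[, 3],
                      stringsAsFactors = FALSE)
  if (identical(unname(tolower(unlist(edges[1, ]))),
                c("source", "relation", "target"))) {
    edges <- edges[-1, , drop = FALSE]
  }
  unknown <- setdiff(unique(edges$relation), .KNOWN_RELATIONS)
  if (length(unknown)) {
    warning(sprintf("unknown relation type(s) kept as-is: %s",
                    paste(unknown, collapse = ", ")))
  }
  .makeGraph(edges)
}

#' Induced subnetwork over a gene list
#'
#' Keeps edges with both endpoints in `genes`; when `dropIsolated`, nodes
#' with no remaining edge are removed, so the returned node count is the
#' size of the connected gene network — the genes that known regulatory or
#' binding relationships actually link together.
#'
#' @param graph an [InteractionGraph-class].
#' @param genes character vector of gene ids.
#' @param dropIsolated drop nodes with no remaining edges (default TRUE).
#' @return an [InteractionGraph-class].
#' @export
inducedSubnetwork <- function(graph, genes, dropIsolated = TRUE) {
  e <- graph@edges
  e <- e[e$source %in% genes & e$target %in% genes, , drop = FALSE]
  nodes <- if (dropIsolated) {
    sort(unique(c(e$source, e$target)))
  } else {
    sort(intersect(graph@nodes, genes))
  }
  .makeGraph(e, nodes = nodes)
}

#' Rank genes by distinct-neighbour connections
#'
#' Counts distinct adjacent genes per node (regardless of direction) plus
#' in/out degree over directed edges, and classifies a regulatory role:
#' sink-like when in-degree > 2 x out-degree (primarily a recipient of
#' regulation), source-like when out-degree > 2 x in-degree, else mixed.
#' Sorted by neighbour count descending, ties alphabetical.
#'
#' @param graph an [InteractionGraph-class].
#' @param roleFactor multiplier in the role rule (default 2).
#' @return data.frame with columns `gene_id`, `n_neighbors`, `in_degree`,
#'   `out_degree`, `role`.
#' @export
rankByNeighbors <- function(graph, roleFactor = 2) {
  nodes <- graph@nodes
  if (!length(nodes)) {
    return(data.frame(gene_id = character(0), n_neighbors = integer(0),
                      in_degree = integer(0), out_degree = integer(0),
                      role = character(0)))
  }
  e <- graph@edges
  nb <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(e)) {
    pairs <- unique(rbind(data.frame(a = e$source, b = e$target),
                          data.frame(a = e$target, b = e$source)))
    cnt <- table(pairs$a)
    nb[names(cnt)] <- as.integer(cnt)
  }
  dIn <- stats::setNames(integer(length(nodes)), nodes)
  dOut <- dIn
  de <- e[e$directed, , drop = FALSE]
  if (nrow(de)) {
    ti <- table(de$target); dIn[names(ti)] <- as.integer(ti)
    to <- table(de$source); dOut[names(to)] <- as.integer(to)
  }
  role <- ifelse(dIn > roleFactor * dOut, "sink-like",
                 ifelse(dOut > roleFactor * dIn, "source-like", "mixed"))
  out <- data.frame(gene_id = nodes, n_neighbors = unname(nb),
                    in_degree = unname(dIn), out_degree = unname(dOut),
                    role = unname(role), stringsAsFactors = FALSE)
  out <- out[order(-out$n_neighbors, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Hub-gene interaction network
#'
#' Intersects the union of module hub genes with the interaction graph's
#' nodes and returns the induced subnetwork over that intersection together
#' with its local-connectivity ranking — the screen for which tightly
#' co-expressed module hubs also sit in the literature-derived regulatory
#' network.
#'
#' @param hubs a hub table from [selectHubs()] (or a character vector of
#'   hub gene ids).
#' @param graph an [InteractionGraph-class] (typically the induced
#'   subnetwork over the full differential-expression union).
#' @return list with `graph` (the hub subnetwork) and `ranking` (from
#'   [rankByNeighbors()]).
#' @export
hubNetwork <- function(hubs, graph) {
  hubGenes <- if (is.data.frame(hubs)) unique(hubs$gene_id) else unique(hubs)
  present <- intersect(hubGenes, graph@nodes)
  sub <- inducedSubnetwork(graph, present, dropIsolated = FALSE)
  list(graph = sub, ranking = rankByNeighbors(sub))
}

#' Convert an interaction graph to igraph
#'
#' Undirected relations are expanded to a single undirected edge attribute;
#' the igraph object is directed with a logical `directed` edge attribute
#' and a `relation` attribute.
#'
#' @param graph an [InteractionGraph-class].
#' @return an `igraph` object.
#' @export
asIgraph <- function(graph) {
  e <- graph@edges[, c("source", "target", "relation", "directed")]
  igraph::graph_from_data_frame(e, directed = TRUE,
                                vertices = data.frame(name = graph@nodes))
}

#' Export an interaction graph as GraphML
#'
#' @param graph an [InteractionGraph-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGraphML <- function(graph, path) {
  igraph::write_graph(asIgraph(graph), path, format = "graphml")
  invisible(path)
}
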