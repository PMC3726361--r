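# Over-representation of gene lists in gene-set collections, pairwise
# signature overlap tables, module-by-treatment cross-tabs, and
# disease-list overlap tests.

#' Gene-set over-representation of a gene list
#'
#' For each set in the collection (intersected with the background first),
#' reports the overlap with the gene list, an "impacted" flag (overlap >=
#' `impactedMin`), the point hypergeometric probability of exactly that
#' overlap, the conventional upper-tail probability P(X >= overlap), and a
#' one-sided (over-representation) Fisher's exact p for the 2x2 table. The
#' point and tail probabilities are reported side by side because some
#' studies quote the probability of obtaining exactly the listed overlap,
#' which is an unusual statistic; the tail and the one-sided Fisher p are
#' mathematically identical.
#'
#' @param geneList character vector of gene ids (subset of background;
#'   genes outside the background are dropped).
#' @param collection named list of gene sets (e.g. from [readGMT()]).
#' @param background character vector: the gene universe (e.g. all genes on
#'   the platform).
#' @param impactedMin minimum overlap for the impacted flag (default 3).
#' @return data.frame with one row per set, sorted by `p_hyper_tail`:
#'   `set_name`, `list_size`, `set_size`, `background_size`, `overlap`,
#'   `impacted`, `p_hyper_point`, `p_hyper_tail`, `p_fisher`.
#' @examples
#' bg <- paste0("g", 1:100)
#' enrichGeneSets(bg[1:10], list(s = bg[6:15]), bg)
#' @export
enrichGeneSets <- function(geneList, collection, background, impactedMin = 3) {
  background <- unique(background)
  if (!length(background)) .invalidArg("background gene universe is empty")
  geneList <- unique(intersect(geneList, background))
  N <- length(background)
  n <- length(geneList)
  rows <- lapply(names(collection), function(nm) {
    set <- unique(intersect(collection[[nm]], background))
    K <- length(set)
    ov <- length(intersect(geneList, set))
    pPoint <- stats::dhyper(ov, K, N - K, n)
    pTail <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    tab <- matrix(c(ov, K - ov, n - ov, N - K - n + ov), 2, 2)
    pFisher <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set_name = nm, list_size = n, set_size = K,
               background_size = N, overlap = ov,
               impacted = ov >= impactedMin,
               p_hyper_point = pPoint, p_hyper_tail = pTail,
               p_fisher = pFisher, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_name = character(0), list_size = integer(0),
                      set_size = integer(0), background_size = integer(0),
                      overlap = integer(0), impacted = logical(0),
                      p_hyper_point = numeric(0), p_hyper_tail = numeric(0),
                      p_fisher = numeric(0))
  }
  out <- out[order(out$p_hyper_tail, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Fisher's exact overlap test for two gene lists
#'
#' Builds the 2x2 table (shared, A-only, B-only, rest of background) and
#' tests over-representation of the overlap one-sidedly. Used e.g. to ask
#' whether a disease gene list (such as genes implicated in primary ovarian
#' insufficiency) overlaps a differential-expression union more than chance.
#'
#' @param listA,listB character vectors of gene ids.
#' @param backgroundN size of the gene universe (must be >= the union size).
#' @return list with `overlap` and `p` (one-sided Fisher's exact p).
#' @export
listOverlapTest <- function(listA, listB, backgroundN) {
  listA <- unique(listA)
  listB <- unique(listB)
  ov <- length(intersect(listA, listB))
  uni <- length(union(listA, listB))
  if (backgroundN < uni) .invalidArg("background smaller than the list union")
  tab <- matrix(c(ov, length(listA) - ov,
                  length(listB) - ov, backgroundN - uni), 2, 2)
  list(overlap = ov,
       p = stats::fisher.test(tab, alternative = "greater")$p.value)
}

#' Pairwise overlap matrix of named gene lists
#'
#' @param lists named list (>= 2) of character vectors.
#' @return list with `counts` (symmetric integer matrix; diagonal = list
#'   sizes) and `fraction` (off-diagonal overlap relative to the smaller
#'   list; diagonal 1).
#' @export
pairwiseOverlap <- function(lists) {
  if (length(lists) < 2) .invalidArg("need at least 2 lists")
  lists <- lapply(lists, unique)
  nm <- names(lists)
  n <- length(lists)
  counts <- matrix(0L, n, n, dimnames = list(nm, nm))
  frac <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    counts[i, i] <- length(lists[[i]])
    for (j in seq_len(n)) {
      if (j <= i) next
      ov <- length(intersect(lists[[i]], lists[[j]]))
      counts[i, j] <- counts[j, i] <- ov
      small <- min(length(lists[[i]]), length(lists[[j]]))
      frac[i, j] <- frac[j, i] <- if (small > 0) ov / small else 0
    }
  }
  list(counts = counts, fraction = frac)
}

#' Pairwise overlap of impacted pathway sets
#'
#' Counts shared impacted set names per pair of gene lists, mirroring the
#' "pathways in common between treatments" summary.
#'
#' @param impacted named list: for each gene list, the character vector of
#'   impacted set names (e.g. `set_name[impacted]` from [enrichGeneSets()]).
#' @return symmetric count matrix with diagonal = number of impacted sets.
#' @export
pathwayOverlap <- function(impacted) {
  if (length(impacted) < 2) .invalidArg("need at least 2 impacted-set lists")
  pairwiseOverlap(impacted)$counts
}

#' Module-by-treatment cross-tabulation
#'
#' Cell (t, m) counts the genes of treatment t's signature assigned to
#' module m (including grey). Row sums equal signature sizes restricted to
#' the assignment's gene universe; column sums equal module sizes restricted
#' to the union of signatures.
#'
#' @param colors named character vector gene id -> module colour (from
#'   [cutModules()] or [moduleColors()]).
#' @param signatures named list of signature data.frames (only rows with
#'   `passes` count) or plain character vectors of gene ids.
#' @return integer matrix, treatments x modules.
#' @export
moduleTreatmentCrosstab <- function(colors, signatures) {
  sigGenes <- lapply(signatures, function(s) {
    if (is.data.frame(s)) s$gene_id[s$passes] else as.character(s)
  })
  mods <- unique(c(setdiff(sort(unique(colors)), "grey"), "grey"))
  out <- matrix(0L, length(sigGenes), length(mods),
                dimnames = list(names(sigGenes), mods))
  for (t in names(sigGenes)) {
    g <- intersect(sigGenes[[t]], names(colors))
    if (!length(g)) next
    tab <- table(factor(colors[g], levels = mods))
    out[t, ] <- as.integer(tab)
  }
  out
}
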