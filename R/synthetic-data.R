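# Synthetic-data generator: expression matrices with planted co-expression
# modules, per-treatment differential-expression effects, a batch effect and
# an optional outlier array, plus the ground truth needed for
# parameter-recovery benchmarks.

# Default treatment labels mirror a seven-factor neonatal ovary culture panel.
.DEFAULT_TREATMENTS <- c("AMH", "CTGF", "E2", "FGF2", "ActivinA", "P4", "TNFa")

#' Simulate a multi-treatment sample design
#'
#' Builds a design table with `repsPerTreatment` replicates of each of
#' `nTreatments` treatments plus `controlReps` control samples. Batches are
#' assigned round-robin over the rows, so batches partition the samples and
#' every batch mixes treatments. The construction is fully deterministic.
#'
#' @param nTreatments number of treatment compounds (default 7).
#' @param repsPerTreatment biological replicates per treatment (default 3).
#' @param controlReps number of control samples (default 7).
#' @param nBatches number of processing batches (default 2).
#' @param treatments optional character vector of treatment names; defaults
#'   to a growth-factor/hormone panel (AMH, CTGF, E2, FGF2, ActivinA, P4,
#'   TNFa) for up to seven treatments.
#' @param seed integer seed, kept for interface symmetry with the stochastic
#'   generators (the design itself is deterministic).
#' @return data.frame with columns `sample_id`, `treatment`, `batch`.
#' @examples
#' d <- simulateDesign()           # 7 x 3 + 7 = 28 samples
#' table(d$treatment)
#' @export
simulateDesign <- function(nTreatments = 7, repsPerTreatment = 3,
                           controlReps = 7, nBatches = 2,
                           treatments = NULL, seed = 1) {
  counts <- c(nTreatments, repsPerTreatment, controlReps, nBatches)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    .invalidArg("all design counts must be positive integers")
  }
  if (is.null(treatments)) {
    treatments <- if (nTreatments <= length(.DEFAULT_TREATMENTS)) {
      .DEFAULT_TREATMENTS[seq_len(nTreatments)]
    } else {
      paste0("T", seq_len(nTreatments))
    }
  }
  if (length(treatments) != nTreatments) {
    .invalidArg("'treatments' must have length nTreatments")
  }
  trt <- c(rep(treatments, each = repsPerTreatment),
           rep("control", controlReps))
  rep_i <- c(unlist(lapply(treatments, function(t) seq_len(repsPerTreatment))),
             seq_len(controlReps))
  n <- length(trt)
  data.frame(
    sample_id = sprintf("%s_r%d", trt, rep_i),
    treatment = trt,
    batch = rep_len(seq_len(nBatches), n),
    stringsAsFactors = FALSE)
}

#' Build a table of planted differential-expression effects
#'
#' Assigns each treatment a signature of `sizes[t]` genes with signed
#' intensity shifts, such that every pair of treatment signatures shares a
#' controlled fraction of genes. Shared genes are drawn as a nested prefix of
#' a common pool, so the pairwise overlap relative to the smaller signature
#' equals `overlapFrac` up to rounding — emulating designs where distinct
#' perturbations of one process regulate largely disjoint gene sets (5-10%
#' pairwise overlap) while signature sizes range from tens to hundreds of
#' genes.
#'
#' Effect sizes are drawn as fold changes in `foldRange` (half the genes
#' down-regulated at the reciprocal fold) and converted to additive shifts on
#' the linear intensity scale around `baseline`.
#'
#' @param design design data.frame from [simulateDesign()].
#' @param geneIds character vector of gene ids to draw from.
#' @param sizes optional named or unnamed vector of signature sizes per
#'   treatment; default draws each uniformly from 50..300.
#' @param overlapFrac target pairwise overlap fraction (default 0.08).
#' @param foldRange range of planted fold changes (default c(1.3, 2)).
#' @param baseline linear-scale baseline intensity (default 100).
#' @param seed integer seed.
#' @return data.frame with columns `treatment`, `gene_id`, `effect` (additive
#'   shift), `fold` (the planted fold change).
#' @export
simulateDeEffects <- function(design, geneIds, sizes = NULL,
                              overlapFrac = 0.08, foldRange = c(1.3, 2),
                              baseline = 100, seed = 1) {
  if (overlapFrac < 0 || overlapFrac > 1) {
    .invalidArg("overlapFrac must be in [0, 1]")
  }
  trts <- setdiff(unique(design$treatment), "control")
  .withSeed(seed, {
    if (is.null(sizes)) {
      sizes <- sample(50:300, length(trts), replace = TRUE)
    }
    sizes <- rep_len(sizes, length(trts))
    shared_n <- round(overlapFrac * sizes)
    perm <- sample(geneIds)
    sMax <- max(shared_n)
    need <- sMax + sum(sizes - shared_n)
    if (need > length(geneIds)) {
      .invalidArg("not enough genes for the requested signature sizes")
    }
    shared <- perm[seq_len(sMax)]
    ptr <- sMax
    rows <- lapply(seq_along(trts), function(i) {
      uniq_n <- sizes[i] - shared_n[i]
      g <- c(if (shared_n[i] > 0) shared[seq_len(shared_n[i])] else character(0),
             perm[ptr + seq_len(uniq_n)])
      ptr <<- ptr + uniq_n
      fold <- stats::runif(sizes[i], foldRange[1], foldRange[2])
      down <- sample(c(TRUE, FALSE), sizes[i], replace = TRUE)
      fold[down] <- 1 / fold[down]
      data.frame(treatment = trts[i], gene_id = g,
                 effect = baseline * (fold - 1), fold = fold,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a gene-by-sample expression matrix with known structure
#'
#' Generative model per gene \eqn{g} and sample \eqn{s} on a linear
#' intensity scale:
#' \deqn{x_{gs} = baseline_g + \lambda_g f_{m(g),s} + \delta_{g,t(s)} +
#'   b_{g,batch(s)} + \epsilon_{gs}}
#' where \eqn{f_{m,s}} is a per-module latent factor drawn once per sample
#' (sd `moduleSignalSd`), \eqn{\lambda_g > 0} are loadings for module
#' members, \eqn{\delta} are planted treatment shifts applied only to the
#' flagged genes of that sample's treatment, \eqn{b} is a per-gene batch
#' offset (sd `batchSd`) and \eqn{\epsilon} is iid Gaussian noise (sd
#' `noiseSd`). Values are clipped at 0. Optionally one treated sample is
#' scaled by `outlierFactor` to plant a QC-detectable outlier array,
#' mirroring a discarded chip.
#'
#' @param design design data.frame (see [simulateDesign()]).
#' @param nGenes total number of genes (default 2000).
#' @param moduleSizes sizes of planted co-expression modules (default spans
#'   20..240, matching module sizes observed in weighted co-expression
#'   studies of this design).
#' @param moduleSignalSd sd of the per-module latent factor (default 20).
#' @param deEffects planted effect table from [simulateDeEffects()], or NULL
#'   to generate one with the defaults, or NA for no treatment effects.
#' @param overlapFrac pairwise signature overlap fraction passed through to
#'   [simulateDeEffects()] when `deEffects` is NULL (default 0.08).
#' @param batchSd sd of per-gene batch offsets (default 5).
#' @param noiseSd sd of iid noise (default 10).
#' @param baseline baseline intensity, scalar or per-gene vector (default 100).
#' @param outlier plant one outlier array? (default TRUE).
#' @param outlierFactor global scale distortion of the outlier array
#'   (default 2.5).
#' @param outlierSample sample id to distort; default: the first P4 replicate
#'   if present, otherwise the first treated sample.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `intensity`, the design as colData, module labels in rowData, and the
#'   full simulation truth in `metadata(.)$truth` (see [simulationTruth()]).
#' @examples
#' d <- simulateDesign()
#' se <- simulateExpression(d, nGenes = 300, moduleSizes = c(60, 40, 20),
#'                          seed = 7)
#' simulationTruth(se)$outlier_sample
#' @export
simulateExpression <- function(design, nGenes = 2000,
                               moduleSizes = c(240, 150, 100, 60, 40, 20),
                               moduleSignalSd = 20, deEffects = NULL,
                               overlapFrac = 0.08, batchSd = 5, noiseSd = 10,
                               baseline = 100, outlier = TRUE,
                               outlierFactor = 2.5, outlierSample = NULL,
                               seed = 1) {
  design <- .designOf(NULL, design)
  if (sum(moduleSizes) > nGenes) .invalidArg("sum(moduleSizes) must be <= nGenes")
  if (any(c(moduleSignalSd, batchSd, noiseSd) < 0)) {
    .invalidArg("standard deviations must be >= 0")
  }
  if (overlapFrac < 0 || overlapFrac > 1) .invalidArg("overlapFrac must be in [0, 1]")

  nS <- nrow(design)
  geneIds <- sprintf("g%0*d", max(4L, nchar(nGenes)), seq_len(nGenes))
  moduleLabel <- integer(nGenes)
  if (length(moduleSizes)) {
    moduleLabel[seq_len(sum(moduleSizes))] <-
      rep(seq_along(moduleSizes), times = moduleSizes)
  }
  baselineG <- rep_len(baseline, nGenes)

  if (is.null(deEffects)) {
    deEffects <- simulateDeEffects(design, geneIds, overlapFrac = overlapFrac,
                                   baseline = mean(baselineG), seed = seed + 1000L)
  } else if (is.atomic(deEffects) && length(deEffects) == 1L && is.na(deEffects)) {
    deEffects <- data.frame(treatment = character(0), gene_id = character(0),
                            effect = numeric(0), fold = numeric(0))
  }
  if (!all(deEffects$gene_id %in% geneIds)) {
    .keyErr("deEffects refers to gene ids not in the simulated gene universe")
  }

  .withSeed(seed, {
    lambda <- stats::runif(nGenes, 0.5, 1.5)
    nMod <- length(moduleSizes)
    f <- matrix(stats::rnorm(max(nMod, 1L) * nS, 0, moduleSignalSd),
                max(nMod, 1L), nS)
    nBatches <- max(design$batch)
    b <- matrix(stats::rnorm(nGenes * nBatches, 0, batchSd), nGenes, nBatches)
    eps <- matrix(stats::rnorm(nGenes * nS, 0, noiseSd), nGenes, nS)

    x <- matrix(baselineG, nGenes, nS) + eps
    inMod <- moduleLabel > 0
    if (any(inMod) && nMod > 0) {
      x[inMod, ] <- x[inMod, ] +
        lambda[inMod] * f[moduleLabel[inMod], , drop = FALSE]
    }
    x <- x + b[, design$batch, drop = FALSE]
    if (nrow(deEffects)) {
      gi <- match(deEffects$gene_id, geneIds)
      for (s in seq_len(nS)) {
        hit <- deEffects$treatment == design$treatment[s]
        if (any(hit)) x[gi[hit], s] <- x[gi[hit], s] + deEffects$effect[hit]
      }
    }

    outSample <- NA_character_
    if (isTRUE(outlier)) {
      if (is.null(outlierSample)) {
        treated <- design$sample_id[design$treatment != "control"]
        p4 <- grep("^P4_", treated, value = TRUE)
        outSample <- if (length(p4)) p4[1] else treated[1]
      } else {
        outSample <- outlierSample
      }
      j <- match(outSample, design$sample_id)
      if (is.na(j)) .keyErr(sprintf("outlierSample '%s' not in design", outSample))
      x[, j] <- x[, j] * outlierFactor
    }
    x[x < 0] <- 0
    dimnames(x) <- list(geneIds, design$sample_id)

    truth <- list(
      module_label = stats::setNames(moduleLabel, geneIds),
      de = deEffects,
      batch_offsets = b,
      outlier_sample = outSample,
      seed = as.integer(seed),
      params = list(nGenes = nGenes, moduleSizes = moduleSizes,
                    moduleSignalSd = moduleSignalSd, overlapFrac = overlapFrac,
                    batchSd = batchSd, noiseSd = noiseSd,
                    baseline = baseline, outlierFactor = outlierFactor))

    SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = x),
      colData = S4Vectors::DataFrame(design, row.names = design$sample_id),
      rowData = S4Vectors::DataFrame(gene_id = geneIds,
                                     module_label = moduleLabel,
                                     loading = lambda),
      metadata = list(truth = truth))
  })
}

#' Ground truth of a simulated experiment
#'
#' @param se a SummarizedExperiment produced by [simulateExpression()].
#' @return list with elements `module_label`, `de`, `batch_offsets`,
#'   `outlier_sample`, `seed`, `params`.
#' @export
simulationTruth <- function(se) {
  truth <- S4Vectors::metadata(se)$truth
  if (is.null(truth)) .keyErr("no simulation truth attached to this object")
  truth
}

#' Simulate a gene annotation table
#'
#' Assigns each gene a symbol or an EST tag (the named-gene flag drives the
#' hub-selection padding rule) and a broad functional category.
#'
#' @param geneIds gene ids.
#' @param namedFrac fraction of genes with a proper symbol (default 0.7).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `symbol`, `named_gene`,
#'   `category`.
#' @export
simulateAnnotation <- function(geneIds, namedFrac = 0.7, seed = 1) {
  cats <- c("metabolism and transport", "signaling",
            "receptors and binding proteins", "transcription",
            "cytoskeleton and ECM", "other")
  .withSeed(seed, {
    named <- stats::runif(length(geneIds)) < namedFrac
    data.frame(
      gene_id = geneIds,
      symbol = ifelse(named, paste0("Sym", sub("^g", "", geneIds)),
                      paste0("EST", sub("^g", "", geneIds))),
      named_gene = named,
      category = ifelse(named, sample(cats[-6], length(geneIds), replace = TRUE),
                        "other"),
      stringsAsFactors = FALSE)
  })
}

# Gene sets for the enrichment stage: one planted set per treatment (drawn
# from that treatment's true signature) plus random sets.
.simulateGeneSets <- function(truth, geneIds, nRandom = 5, seed = 1) {
  .withSeed(seed, {
    sets <- list()
    for (t in unique(truth$de$treatment)) {
      g <- truth$de$gene_id[truth$de$treatment == t]
      sets[[paste0("planted_", t)]] <- g[seq_len(min(20L, length(g)))]
    }
    for (i in seq_len(nRandom)) {
      sets[[sprintf("random_set_%02d", i)]] <-
        sample(geneIds, sample(15:40, 1))
    }
    sets
  })
}

# SIF-like interaction edge list among a subset of genes, biased toward the
# planted signature genes so induced subnetworks are non-trivial.
.simulateEdges <- function(truth, geneIds, nNodes = 250, edgesPerNode = 3,
                           seed = 1) {
  rels <- c("regulation", "expression", "promoter-binding",
            "protein-modification", "binding")
  .withSeed(seed, {
    deGenes <- unique(truth$de$gene_id)
    nodes <- unique(c(deGenes[seq_len(min(length(deGenes), round(0.8 * nNodes)))],
                      sample(geneIds, nNodes)))[seq_len(min(nNodes, length(geneIds)))]
    m <- edgesPerNode * length(nodes)
    e <- data.frame(source = sample(nodes, m, replace = TRUE),
                    relation = sample(rels, m, replace = TRUE),
                    target = sample(nodes, m, replace = TRUE),
                    stringsAsFactors = FALSE)
    e <- e[e$source != e$target, ]
    e[!duplicated(e), ]
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates a design, expression matrix, annotation, GMT gene-set
#' collection, interaction edge list and truth JSON, and writes them as
#' plain-text files. Re-running with the same seed reproduces byte-identical
#' files.
#'
#' @param dir output directory (created if missing).
#' @param design optional design; default [simulateDesign()].
#' @param nGenes,seed,... passed to [simulateExpression()].
#' @return named character vector of the six file paths (`expression`,
#'   `design`, `annotation`, `gmt`, `edges`, `truth`).
#' @export
writeFixtureBundle <- function(dir, design = NULL, nGenes = 2000, seed = 1, ...) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .ioErr(sprintf("cannot create directory '%s'", dir))
  }
  if (file.access(dir, 2) != 0) .ioErr(sprintf("directory '%s' is not writable", dir))
  if (is.null(design)) design <- simulateDesign(seed = seed)
  se <- simulateExpression(design, nGenes = nGenes, seed = seed, ...)
  truth <- simulationTruth(se)
  geneIds <- rownames(se)
  ann <- simulateAnnotation(geneIds, seed = seed + 2000L)
  sets <- .simulateGeneSets(truth, geneIds, seed = seed + 3000L)
  edges <- .simulateEdges(truth, geneIds, seed = seed + 4000L)

  paths <- c(expression = file.path(dir, "expression.tsv"),
             design = file.path(dir, "design.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             gmt = file.path(dir, "gene_sets.gmt"),
             edges = file.path(dir, "edges.tsv"),
             truth = file.path(dir, "truth.json"))
  writeExpression(se, paths["expression"])
  .writeTSV(as.data.frame(SummarizedExperiment::colData(se))[,
            c("sample_id", "treatment", "batch")], paths["design"])
  .writeTSV(ann, paths["annotation"])
  writeGMT(sets, paths["gmt"])
  .writeTSV(edges, paths["edges"])
  truthOut <- truth
  truthOut$module_label <- as.list(truth$module_label)
  truthOut$batch_offsets <- NULL   # bulky and recomputable from the seed
  jsonlite::write_json(truthOut, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
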