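# Pipeline configuration and the end-to-end orchestration: QC -> batch
# centering -> signatures -> union -> soft-threshold selection -> adjacency
# -> TOM -> modules -> k.in -> hubs -> enrichment -> overlap tables ->
# interaction subnetworks, with a JSON run manifest.

#' Build a validated pipeline configuration
#'
#' Defaults follow the analysis conventions this pipeline encodes: fold
#' change 1.2/0.83, p 0.05, absolute difference 10; truncated scale-free
#' R-squared threshold 0.75 over powers 1..20; minimum module size 20; hub
#' top fraction 10% with k.in floor 8; impacted-pathway minimum 3.
#'
#' @param expression path to the expression TSV.
#' @param design path to the design TSV.
#' @param outdir output directory.
#' @param annotation,gmt,edges optional paths (annotation TSV, GMT
#'   collection, SIF-like edge list). Stages needing a missing input are
#'   skipped.
#' @param criteria a [deCriteria()] list.
#' @param qcThreshold KS-distance flag threshold (default 0.25).
#' @param dropOutliers drop flagged arrays (default TRUE).
#' @param doBatchCenter mean-center batches before testing (default TRUE).
#' @param betas soft-threshold scan range (default 1:20).
#' @param r2Min scale-free qualification threshold (default 0.75).
#' @param nBins connectivity bins for the fit (default 10).
#' @param minSize,cutHeightFrac module-cut parameters (defaults 20, 0.99).
#' @param hubFraction,kinFloor hub-selection parameters (defaults 0.10, 8).
#' @param impactedMin impacted-pathway minimum overlap (default 3).
#' @param seed integer seed controlling every stochastic step.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(expression, design, outdir,
                           annotation = NULL, gmt = NULL, edges = NULL,
                           criteria = deCriteria(), qcThreshold = 0.25,
                           dropOutliers = TRUE, doBatchCenter = TRUE,
                           betas = 1:20, r2Min = 0.75, nBins = 10,
                           minSize = 20, cutHeightFrac = 0.99,
                           hubFraction = 0.10, kinFloor = 8,
                           impactedMin = 3, seed = 1) {
  for (p in c(expression, design, annotation, gmt, edges)) {
    if (!is.null(p) && !file.exists(p)) .ioErr(sprintf("input not found: %s", p))
  }
  structure(list(expression = expression, design = design, outdir = outdir,
                 annotation = annotation, gmt = gmt, edges = edges,
                 criteria = criteria, qcThreshold = qcThreshold,
                 dropOutliers = dropOutliers, doBatchCenter = doBatchCenter,
                 betas = betas, r2Min = r2Min, nBins = nBins,
                 minSize = minSize, cutHeightFrac = cutHeightFrac,
                 hubFraction = hubFraction, kinFloor = kinFloor,
                 impactedMin = impactedMin, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; `criteria` may be
#' a mapping with `fcUp`/`fcDown`/`pMax`/`minAbsDiff`. Explicit `overrides`
#' (e.g. from command-line flags) take precedence over the file, which takes
#' precedence over the defaults.
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) .ioErr(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$criteria) && !inherits(cfg$criteria, "DECriteria")) {
    cfg$criteria <- do.call(deCriteria, cfg$criteria)
  }
  if (!is.null(cfg$betas) && length(cfg$betas) == 2L) {
    cfg$betas <- seq(cfg$betas[1], cfg$betas[2])
  }
  do.call(pipelineConfig, cfg)
}

.stageLog <- function(verbose, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

.stage <- function(name, verbose, expr) {
  .stageLog(verbose, "stage %s", name)
  tryCatch(expr, error = function(e) {
    .anErr(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           "pipelineStageError")
  })
}

#' Run the full bionetwork pipeline
#'
#' Executes QC, optional batch centering, per-treatment signature lists,
#' their union, soft-threshold selection, adjacency and topological overlap
#' on the union genes, module detection, within-module connectivity, hub
#' selection, gene-set enrichment, overlap tables, the module-by-treatment
#' cross-tab and interaction subnetworks, writing every result as TSV /
#' GraphML / Newick under `config$outdir` plus a JSON run manifest. All
#' outputs are deterministic given the inputs and seed.
#'
#' @param config a [pipelineConfig()] list.
#' @param verbose log stage progress to stderr (default FALSE).
#' @return (invisibly) a list with the in-memory results: `qc`,
#'   `signatures`, `union`, `betaPick`, `network`, `tom`, `modules`,
#'   `hubs`, `enrichment`, `overlaps`, `crosstab`, `graph`, `hubNet`,
#'   `manifest`, `paths`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "PipelineConfig")) .invalidArg("config must be a PipelineConfig")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  counts <- list()

  design <- .stage("read-design", verbose, readDesign(config$design))
  m <- .stage("read-expression", verbose, readExpression(config$expression))
  background <- rownames(m)

  qc <- .stage("qc", verbose, flagOutlierArrays(m, config$qcThreshold))
  paths$qc <- .writeTSV(qc, file.path(config$outdir, "qc_flags.tsv"))
  if (config$dropOutliers && any(qc$flagged)) {
    m <- m[, !colnames(m) %in% qc$sample_id[qc$flagged], drop = FALSE]
    design <- design[design$sample_id %in% colnames(m), ]
  }
  counts$samples_retained <- ncol(m)

  if (config$doBatchCenter && length(unique(design$batch)) > 1) {
    m <- .stage("batch-center", verbose, batchCenter(m, design))
  }

  sigs <- .stage("signatures", verbose,
                 deSignatures(m, design, config$criteria))
  sigDir <- file.path(config$outdir, "signatures")
  dir.create(sigDir, showWarnings = FALSE)
  for (t in names(sigs)) {
    .writeTSV(sigs[[t]], file.path(sigDir, paste0(t, ".tsv")))
  }
  paths$signatures <- sigDir
  counts$signature_sizes <- vapply(sigs, function(s) sum(s$passes), integer(1))

  uni <- .stage("union", verbose, unionSignatures(sigs))
  paths$union <- .writeTSV(uni, file.path(config$outdir, "union.tsv"))
  counts$union_genes <- nrow(uni)

  net <- tomObj <- modules <- hubs <- NULL
  betaPick <- NULL
  if (nrow(uni) >= 3) {
    corr <- .stage("correlation", verbose, correlationMatrix(m, uni$gene_id))
    betaPick <- .stage("pick-beta", verbose,
                       pickBeta(corr, config$betas, config$r2Min, config$nBins))
    paths$betaScan <- .writeTSV(betaPick$scan,
                                file.path(config$outdir, "beta_scan.tsv"))
    net <- .stage("adjacency", verbose,
                  powerAdjacency(corr, betaPick$beta, scan = betaPick$scan))
    tomObj <- .stage("tom", verbose, topologicalOverlap(net))
    modules <- .stage("modules", verbose,
                      detectModules(tomObj, net, config$minSize,
                                    config$cutHeightFrac))
    paths$dendrogram <- writeDendrogramNewick(
      modules@dendrogram, file.path(config$outdir, "dendrogram.nwk"))
    counts$modules <- length(moduleSizes(modules))
    counts$grey_genes <- sum(moduleColors(modules) == "grey")

    ann <- if (!is.null(config$annotation)) {
      readAnnotation(config$annotation)
    } else {
      data.frame(gene_id = background,
                 symbol = background, named_gene = TRUE)
    }
    modTab <- connectivityTable(modules)
    if (counts$modules > 0) {
      hubs <- .stage("hubs", verbose,
                     selectHubs(modules, ann, config$hubFraction,
                                config$kinFloor))
      hubFlag <- paste(modTab$gene_id, modTab$module_color) %in%
        paste(hubs$gene_id, hubs$module_color)
      reason <- stats::setNames(hubs$reason,
                                paste(hubs$gene_id, hubs$module_color))
      modTab$hub_flag <- hubFlag
      modTab$reason <- ifelse(hubFlag,
                              reason[paste(modTab$gene_id, modTab$module_color)],
                              "")
      counts$hubs <- nrow(hubs)
    } else {
      modTab$hub_flag <- FALSE
      modTab$reason <- ""
      warning("no module reached the minimum size; all genes are grey")
    }
    paths$modules <- .writeTSV(modTab,
                               file.path(config$outdir, "modules.tsv"))
  } else {
    warning("union too small for network construction; network stages skipped")
  }

  enrichment <- NULL
  overlaps <- list()
  if (!is.null(config$gmt)) {
    collection <- .stage("read-gmt", verbose, readGMT(config$gmt))
    enrichment <- .stage("enrich", verbose, {
      lists <- c(list(union = uni$gene_id),
                 lapply(sigs, function(s) s$gene_id[s$passes]))
      if (!is.null(modules)) {
        cols <- moduleColors(modules)
        for (cl in names(moduleSizes(modules))) {
          lists[[paste0("module_", cl)]] <- names(cols)[cols == cl]
        }
      }
      lapply(lists, enrichGeneSets, collection = collection,
             background = background, impactedMin = config$impactedMin)
    })
    enrDir <- file.path(config$outdir, "enrichment")
    dir.create(enrDir, showWarnings = FALSE)
    for (nm in names(enrichment)) {
      .writeTSV(enrichment[[nm]], file.path(enrDir, paste0(nm, ".tsv")))
    }
    paths$enrichment <- enrDir
    impacted <- lapply(names(sigs), function(t) {
      e <- enrichment[[t]]
      e$set_name[e$impacted]
    })
    names(impacted) <- names(sigs)
    overlaps$pathways <- .stage("pathway-overlap", verbose,
                                pathwayOverlap(impacted))
    paths$pathwayOverlap <- writeOverlapMatrix(
      overlaps$pathways, file.path(config$outdir, "overlap_pathways.tsv"))
  }

  sigLists <- lapply(sigs, function(s) s$gene_id[s$passes])
  overlaps$genes <- .stage("gene-overlap", verbose, pairwiseOverlap(sigLists))
  paths$geneOverlap <- writeOverlapMatrix(
    overlaps$genes$counts, file.path(config$outdir, "overlap_genes.tsv"))
  paths$geneOverlapFrac <- writeOverlapMatrix(
    round(overlaps$genes$fraction, 6),
    file.path(config$outdir, "overlap_genes_frac.tsv"))

  crosstab <- NULL
  if (!is.null(modules)) {
    crosstab <- .stage("crosstab", verbose,
                       moduleTreatmentCrosstab(moduleColors(modules), sigs))
    paths$crosstab <- writeOverlapMatrix(
      crosstab, file.path(config$outdir, "crosstab.tsv"))
  }

  graph <- hubNet <- NULL
  if (!is.null(config$edges)) {
    g <- .stage("read-edges", verbose, readEdgeList(config$edges))
    graph <- .stage("induced-subnetwork", verbose,
                    inducedSubnetwork(g, uni$gene_id))
    ranking <- rankByNeighbors(graph)
    paths$networkRanking <- .writeTSV(
      ranking, file.path(config$outdir, "network_ranking.tsv"))
    paths$networkGraphml <- writeGraphML(
      graph, file.path(config$outdir, "network.graphml"))
    counts$network_nodes <- length(graphNodes(graph))
    if (!is.null(hubs)) {
      hubNet <- .stage("hub-network", verbose, hubNetwork(hubs, graph))
      paths$hubRanking <- .writeTSV(
        hubNet$ranking, file.path(config$outdir, "hub_network_ranking.tsv"))
      counts$hub_network_nodes <- length(graphNodes(hubNet$graph))
    }
  }

  # paths are stored relative to outdir so the manifest (and its checksum)
  # does not depend on where the run was written
  relPaths <- lapply(paths, function(p) {
    sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", config$outdir), "/?"),
        "", as.character(p))
  })
  manifest <- list(
    config = config[setdiff(names(config), c("criteria", "outdir"))],
    criteria = unclass(config$criteria),
    seed = config$seed,
    versions = list(assemblyNet = as.character(utils::packageVersion("assemblyNet")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    beta = if (!is.null(betaPick)) betaPick$beta else NA,
    beta_qualified = if (!is.null(betaPick)) betaPick$qualified else NA,
    counts = counts,
    outputs = relPaths)
  paths$manifest <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(qc = qc, signatures = sigs, union = uni, betaPick = betaPick,
                 network = net, tom = tomObj, modules = modules, hubs = hubs,
                 enrichment = enrichment, overlaps = overlaps,
                 crosstab = crosstab, graph = graph, hubNet = hubNet,
                 manifest = manifest, paths = paths))
}
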