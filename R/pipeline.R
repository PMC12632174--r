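## End-to-end orchestration: a single config drives simulate/load -> QC ->
## log-normalization -> HVG/PCA/kNN/Leiden -> annotation -> DGE ->
## scoring -> connectome -> ligand activity, with per-stage seeds, a
## hashed run manifest, and summary-table export.

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the pipeline in one list, with the published
#' workflow's thresholds as defaults: gene filter (>= 1 count, >= 5
#' cells), cell filter (mito < 10%, >= 300 genes, >= 500 counts), 50 PCs,
#' Wilcoxon marker and Welch DGE thresholds (q < 0.05, |log2FC| > 0.5,
#' >= 10 expressing cells), and the ligand filters (>= 10% sender cells,
#' PCC > 0.05).
#'
#' @param sim Optional [SimConfig-class]: simulate the input atlas.
#' @param countsDir,metaFile Optional paths to a Matrix Market counts
#'   directory and cell-metadata TSV (used when `sim` is `NULL`).
#' @param lrFile,priorFile,gmtFile Optional resource paths
#'   (ligand-receptor TSV, regulatory-potential TSV, gene sets GMT).
#'   With a simulated atlas and no paths, matched resources are generated
#'   from the planted truth.
#' @param outDir Output directory.
#' @param detectDoublets Run doublet detection and remove flagged cells.
#' @param normalize `"cp10k"` or `"none"` (log1p only).
#' @param minGeneCount,minCellsPerGene Gene filter.
#' @param maxMitoFraction,minGenesPerCell,minCountsPerCell Cell filter.
#' @param nHVG,kNN,nPCs,resolution Clustering parameters.
#' @param minCellsExpressing,lfcUp,lfcDown,fdr DGE thresholds.
#' @param senderFraction,pccMin Ligand-activity filters.
#' @param nDecoyPairs,nDecoyLigands Decoy resource sizes (simulated runs).
#' @param seed Global seed, expanded per stage via [stageSeed()].
#' @return A validated configuration list of class `circuitscan_config`.
#' @export
pipelineConfig <- function(sim = NULL, countsDir = NULL, metaFile = NULL,
                           lrFile = NULL, priorFile = NULL, gmtFile = NULL,
                           outDir = tempfile("circuitscan_"),
                           detectDoublets = TRUE,
                           normalize = c("cp10k", "none"),
                           minGeneCount = 1L, minCellsPerGene = 5L,
                           maxMitoFraction = 0.10, minGenesPerCell = 300L,
                           minCountsPerCell = 500L,
                           nHVG = 2000L, kNN = 15L, nPCs = 50L,
                           resolution = 1.0,
                           minCellsExpressing = 10L, lfcUp = 0.5,
                           lfcDown = -0.5, fdr = 0.05,
                           senderFraction = 0.10, pccMin = 0.05,
                           nDecoyPairs = 50L, nDecoyLigands = 50L,
                           seed = 1L) {
  normalize <- match.arg(normalize)
  if (is.null(sim) && is.null(countsDir))
    stop("either a simulation config or a counts directory is required")
  if (!is.null(sim)) {
    stopifnot(methods::is(sim, "SimConfig"))
    methods::validObject(sim)
  }
  for (p in c(countsDir, metaFile, lrFile, priorFile, gmtFile)) {
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  }
  stopifnot(maxMitoFraction >= 0, maxMitoFraction <= 1,
            fdr > 0, fdr < 1, lfcUp > 0, lfcDown < 0,
            senderFraction >= 0, senderFraction <= 1)
  cfg <- list(sim = sim, countsDir = countsDir, metaFile = metaFile,
              lrFile = lrFile, priorFile = priorFile, gmtFile = gmtFile,
              outDir = outDir, detectDoublets = detectDoublets,
              normalize = normalize, minGeneCount = minGeneCount,
              minCellsPerGene = minCellsPerGene,
              maxMitoFraction = maxMitoFraction,
              minGenesPerCell = minGenesPerCell,
              minCountsPerCell = minCountsPerCell, nHVG = nHVG, kNN = kNN,
              nPCs = nPCs, resolution = resolution,
              minCellsExpressing = minCellsExpressing, lfcUp = lfcUp,
              lfcDown = lfcDown, fdr = fdr,
              senderFraction = senderFraction, pccMin = pccMin,
              nDecoyPairs = nDecoyPairs, nDecoyLigands = nDecoyLigands,
              seed = as.integer(seed))
  class(cfg) <- "circuitscan_config"
  cfg
}

.manifestRow <- function(stage, files, seed, secs) {
  if (!length(files)) files <- NA_character_
  data.frame(stage = stage, output = files,
             md5 = ifelse(is.na(files), NA_character_,
                          unname(tools::md5sum(files))),
             seed = seed, seconds = round(secs, 3))
}

#' Run the full pipeline
#'
#' Executes the stages in the reference order (QC -> log -> HVG ->
#' PCA/kNN -> Leiden -> annotation -> DGE -> scoring -> connectome ->
#' ligand activity), writing each stage's tables under `config$outDir`
#' and recording a manifest with output hashes and per-stage seeds.
#' Reruns with an identical config reproduce identical hashes for every
#' deterministic stage.
#'
#' @param config A configuration from [pipelineConfig()].
#' @param verbose Print per-stage progress.
#' @return A list with `sce` (annotated, filtered), `markers`, `dge`,
#'   `effectSummary`, `scores` (if gene sets were supplied), `circuits`
#'   (per-treatment list with connectome/ligands/report), `qcLog`
#'   (attrition counts), and `manifest`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "circuitscan_config"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  qcLog <- list()
  note <- function(...) if (verbose) message(...)
  tick <- function(stage, files, seed, t0) {
    manifest[[stage]] <<- .manifestRow(stage, files, seed,
                                       as.numeric(Sys.time()) - t0)
  }

  ## -- input ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  reference <- NULL; truth <- NULL; resources <- NULL
  if (!is.null(config$sim)) {
    note("simulating atlas")
    sim <- simulateAtlas(config$sim)
    sce <- sim$sce
    truth <- sim$truth
    reference <- sim$reference
    if (config$sim@doubletRate > 0)
      sce <- injectDoublets(sce, config$sim@doubletRate,
                            seed = stageSeed(config$seed, "doublet-inject"))
  } else {
    note("loading counts from ", config$countsDir)
    sce <- readCountsMM(config$countsDir, meta = config$metaFile)
  }
  if (!"treatment" %in% names(SummarizedExperiment::colData(sce)))
    stop("cell metadata must declare a 'treatment' column")
  if (!"sham" %in% sce$treatment)
    stop("no 'sham' cells present; the control condition is required")
  tick("input", character(), config$seed, t0)
  qcLog$cells_in <- ncol(sce); qcLog$genes_in <- nrow(sce)

  ## -- QC ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sce <- filterGenes(sce, config$minGeneCount, config$minCellsPerGene)
  qcLog$genes_after_filter <- nrow(sce)
  if (config$detectDoublets && ncol(sce) >= 50L) {
    sc <- detectDoublets(sce, seed = stageSeed(config$seed, "scrublet"))
    thr <- doubletThreshold(sc)
    sce$doublet_score <- as.numeric(sc)
    keep <- sc < thr
    qcLog$doublets_removed <- sum(!keep)
    sce <- sce[, keep]
  } else {
    qcLog$doublets_removed <- 0L
  }
  sce <- filterCells(sce, config$maxMitoFraction, config$minGenesPerCell,
                     config$minCountsPerCell)
  qcLog$cells_after_filter <- ncol(sce)
  qcFile <- file.path(config$outDir, "qc_cells.tsv")
  writeCellMeta(sce, qcFile)
  tick("qc", qcFile, stageSeed(config$seed, "scrublet"), t0)

  ## -- normalize ------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  sce <- logNormalize(sce, method = config$normalize)
  tick("normalize", character(), config$seed, t0)

  ## -- cluster + annotate ---------------------------------------------
  t0 <- as.numeric(Sys.time())
  hv <- consensusHVGs(sce, nTop = config$nHVG)
  eg <- embedGraph(sce, hv$consensus, nPCs = config$nPCs, k = config$kNN)
  clusters <- clusterLeiden(eg$graph, resolution = config$resolution,
                            seed = stageSeed(config$seed, "leiden"))
  if (is.null(reference)) reference <- markerReference()
  sce <- tryCatch(annotateTypes(sce, clusters, reference,
                                seed = stageSeed(config$seed, "annotate")),
                  error = function(e) {
                    warning("annotation fell back to cluster ids: ",
                            conditionMessage(e))
                    sce$cluster <- as.character(clusters)
                    sce$cell_type <- paste0("cluster", clusters)
                    sce
                  })
  markers <- rankMarkers(sce, sce$cell_type, fdr = config$fdr,
                         lfc = config$lfcUp)
  markerFile <- file.path(config$outDir, "markers.tsv")
  write.table(markers, markerFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  clusterFile <- file.path(config$outDir, "cells_annotated.tsv")
  writeCellMeta(sce, clusterFile)
  tick("cluster", c(markerFile, clusterFile),
       stageSeed(config$seed, "leiden"), t0)

  ## -- DGE -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dge <- withCallingHandlers(
    dgePerCellType(sce, minCellsExpressing = config$minCellsExpressing,
                   lfcUp = config$lfcUp, lfcDown = config$lfcDown,
                   fdr = config$fdr),
    warning = function(w) invokeRestart("muffleWarning"))
  eff <- effectSizeSummary(dge)
  dgeFile <- file.path(config$outDir, "dge.tsv")
  effFile <- file.path(config$outDir, "effect_size_summary.tsv")
  write.table(dge, dgeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(eff, effFile, sep = "\t", quote = FALSE, row.names = FALSE)
  tick("dge", c(dgeFile, effFile), config$seed, t0)

  ## -- scoring ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  scores <- NULL
  scoreFiles <- character()
  if (!is.null(config$gmtFile)) {
    sets <- readGMT(config$gmtFile)
    scores <- vapply(names(sets), function(nm)
      scoreGeneSet(sce, sets[[nm]],
                   seed = stageSeed(config$seed, paste0("score-", nm))),
      numeric(ncol(sce)))
    scoreFiles <- file.path(config$outDir, "signature_scores.tsv")
    write.table(data.frame(barcode = colnames(sce), scores),
                scoreFiles, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("score", scoreFiles, config$seed, t0)

  ## -- circuits ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$lrFile)) {
    lrPairs <- readLRPairs(config$lrFile)
    prior <- readRegPotential(config$priorFile)
  } else if (!is.null(truth)) {
    resources <- makeLRResources(truth, rownames(sce),
                                 nDecoyPairs = config$nDecoyPairs,
                                 nDecoyLigands = config$nDecoyLigands,
                                 seed = stageSeed(config$seed, "resources"))
    lrPairs <- resources$lrPairs
    prior <- resources$regPotential
  } else {
    lrPairs <- NULL
  }
  circuits <- NULL
  circuitFiles <- character()
  if (!is.null(lrPairs) && nrow(dge)) {
    treatments <- unique(dge$treatment)
    circuits <- lapply(setNames(treatments, treatments), function(tr)
      inferCircuits(sce, dge, lrPairs, prior, tr,
                    minSenderFrac = config$senderFraction,
                    minPcc = config$pccMin, lfc = config$lfcUp,
                    fdr = config$fdr))
    for (tr in names(circuits)) {
      pre <- file.path(config$outDir, paste0("connectome_", tr))
      writeConnectome(circuits[[tr]]$connectome, pre)
      repFile <- file.path(config$outDir, paste0("circuits_", tr, ".tsv"))
      write.table(circuits[[tr]]$circuits, repFile, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      circuitFiles <- c(circuitFiles, paste0(pre, "_edges.tsv"), repFile)
    }
  }
  tick("circuits", circuitFiles, config$seed, t0)

  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  manifestFile <- file.path(config$outDir, "manifest.tsv")
  write.table(manifest, manifestFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(sce = sce, truth = truth, reference = reference, hvgs = hv,
       markers = markers, dge = dge, effectSummary = eff, scores = scores,
       circuits = circuits, resources = resources, qcLog = qcLog,
       manifest = manifest)
}

#' Export long-format expression-browser tables
#'
#' Tidy per-(gene, cell type, treatment) tables combining dot-plot
#' statistics (fraction expressing, mean expression) with the DGE
#' statistics where available — the substrate of an expression-browser
#' view of genes of interest. Unknown genes are reported in an
#' `unmatched` element, never silently dropped.
#'
#' @param sce Annotated `SingleCellExperiment`.
#' @param dge DGE table from [dgePerCellType()].
#' @param genes Genes of interest.
#' @param file Optional TSV output path.
#' @return `list(table, unmatched)`; the table has one row per matched
#'   (gene, cell type, treatment).
#' @export
exportToxAtlasTables <- function(sce, dge, genes, file = NULL) {
  unmatched <- setdiff(genes, rownames(sce))
  genes <- intersect(genes, rownames(sce))
  if (!length(genes))
    return(list(table = data.frame(), unmatched = unmatched))
  tab <- dotplotStats(sce, genes)
  dcols <- c("log2FC", "p", "q", "direction")
  m <- match(paste(tab$cell_type, tab$treatment, tab$gene),
             paste(dge$cell_type, dge$treatment, dge$gene))
  for (cc in dcols) tab[[cc]] <- dge[[cc]][m]
  if (!is.null(file))
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  list(table = tab, unmatched = unmatched)
}
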