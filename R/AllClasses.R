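#' Simulation configuration for the perturbation atlas generator
#'
#' An S4 container holding every knob of the negative-binomial perturbation
#' simulator: the atlas layout (cell types, samples, treatments), the count
#' law (NB mean scale and dispersion, lognormal cell size factors), planted
#' marker structure, artifact rates, and the planted treatment-specific
#' circuits and differential-expression programs that constitute the ground
#' truth.
#'
#' @slot nCellTypes Number of planted cell types.
#' @slot nGenes Total number of genes in the simulated universe.
#' @slot cellsPerSampleType Cells per (sample, cell type) block.
#' @slot samplesPerTreatment Biological replicates per treatment.
#' @slot treatments Treatment labels; must include `"sham"`.
#' @slot baseMean Baseline NB mean per gene per cell (before size factors).
#' @slot nbDispersion NB dispersion; variance = mu + dispersion * mu^2.
#' @slot markerGenesPerType Exclusive marker genes planted per cell type.
#' @slot markerFold Fold-change of marker genes over baseline.
#' @slot doubletRate Fraction of doublets injected by [injectDoublets()].
#' @slot mitoGeneFraction Fraction of genes in the mitochondrial block
#'   (named with the mouse `mt-` prefix).
#' @slot targetsPerCircuit Downstream target genes induced in the receiver
#'   cell type of every planted circuit.
#' @slot circuits `data.frame` with columns `treatment`, `sender_type`,
#'   `ligand`, `receiver_type`, `receptor`, `log2_effect`.
#' @slot deGenes `data.frame` with columns `treatment`, `cell_type`,
#'   `gene`, `log2_effect`: extra planted DE genes outside circuits.
#' @slot seed Integer seed; identical configs give identical atlases.
#' @seealso [simConfig()], [simulateAtlas()]
#' @export
setClass("SimConfig", representation(
  nCellTypes = "integer",
  nGenes = "integer",
  cellsPerSampleType = "integer",
  samplesPerTreatment = "integer",
  treatments = "character",
  baseMean = "numeric",
  nbDispersion = "numeric",
  markerGenesPerType = "integer",
  markerFold = "numeric",
  doubletRate = "numeric",
  mitoGeneFraction = "numeric",
  targetsPerCircuit = "integer",
  circuits = "data.frame",
  deGenes = "data.frame",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(nCellTypes = object@nCellTypes, nGenes = object@nGenes,
           cellsPerSampleType = object@cellsPerSampleType,
           samplesPerTreatment = object@samplesPerTreatment,
           markerGenesPerType = object@markerGenesPerType)
  if (any(cnt < 1L)) msg <- c(msg, "all count parameters must be >= 1")
  if (!"sham" %in% object@treatments)
    msg <- c(msg, "'sham' must be among the treatments")
  if (anyDuplicated(object@treatments))
    msg <- c(msg, "treatment labels must be unique")
  if (object@doubletRate < 0 || object@doubletRate >= 0.5)
    msg <- c(msg, "doubletRate must lie in [0, 0.5)")
  if (object@mitoGeneFraction < 0 || object@mitoGeneFraction > 1)
    msg <- c(msg, "mitoGeneFraction must lie in [0, 1]")
  if (object@baseMean <= 0 || object@nbDispersion <= 0 || object@markerFold <= 0)
    msg <- c(msg, "baseMean, nbDispersion and markerFold must be positive")
  need <- c("treatment", "sender_type", "ligand", "receiver_type",
            "receptor", "log2_effect")
  if (!all(need %in% names(object@circuits)))
    msg <- c(msg, paste("circuits needs columns:", paste(need, collapse = ", ")))
  needDe <- c("treatment", "cell_type", "gene", "log2_effect")
  if (!all(needDe %in% names(object@deGenes)))
    msg <- c(msg, paste("deGenes needs columns:", paste(needDe, collapse = ", ")))
  if (nrow(object@circuits) && any(object@circuits$log2_effect == 0))
    msg <- c(msg, "planted circuit log2_effect must be nonzero")
  if (nrow(object@deGenes) && any(object@deGenes$log2_effect == 0))
    msg <- c(msg, "planted deGenes log2_effect must be nonzero")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults emulate the study design the simulator stands in for: five
#' instillation conditions (sham, CNP, DWCNT, MWCNT, LPS) with replicate
#' animals per condition, a multi-lineage lung cell-type panel, and
#' treatment-specific cytokine circuits (e.g. CNP driving *Cxcl1* from AT2
#' cells toward *Cxcr2*-bearing lipofibroblasts) planted at a 1.5 log2
#' fold-change.
#'
#' @param nCellTypes,nGenes,cellsPerSampleType,samplesPerTreatment Atlas
#'   layout; defaults give roughly 2,000 cells by 1,500 genes.
#' @param treatments Treatment labels, must include `"sham"`.
#' @param baseMean,nbDispersion NB count law (mean scale and dispersion).
#' @param markerGenesPerType,markerFold Planted cell-type marker structure.
#' @param doubletRate Doublet fraction used by [injectDoublets()].
#' @param mitoGeneFraction Fraction of genes forming the `mt-` block.
#' @param targetsPerCircuit Receiver response genes per planted circuit.
#' @param circuits,deGenes Planted ground-truth programs; see
#'   [SimConfig-class]. `NULL` selects the built-in defaults (`circuits`)
#'   or an empty table (`deGenes`).
#' @param seed Integer seed.
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(nGenes = 300, cellsPerSampleType = 20, seed = 1)
#' cfg
simConfig <- function(nCellTypes = 8L,
                      nGenes = 1500L,
                      cellsPerSampleType = 25L,
                      samplesPerTreatment = 2L,
                      treatments = c("sham", "CNP", "DWCNT", "MWCNT", "LPS"),
                      baseMean = 1,
                      nbDispersion = 0.5,
                      markerGenesPerType = 20L,
                      markerFold = 5,
                      doubletRate = 0.05,
                      mitoGeneFraction = 10 / nGenes,
                      targetsPerCircuit = 20L,
                      circuits = NULL,
                      deGenes = NULL,
                      seed = 1L) {
  if (is.null(circuits)) {
    circuits <- defaultCircuits(treatments)
  }
  if (is.null(deGenes)) {
    deGenes <- data.frame(treatment = character(), cell_type = character(),
                          gene = character(), log2_effect = numeric())
  }
  methods::new("SimConfig",
    nCellTypes = as.integer(nCellTypes), nGenes = as.integer(nGenes),
    cellsPerSampleType = as.integer(cellsPerSampleType),
    samplesPerTreatment = as.integer(samplesPerTreatment),
    treatments = treatments, baseMean = baseMean,
    nbDispersion = nbDispersion,
    markerGenesPerType = as.integer(markerGenesPerType),
    markerFold = markerFold, doubletRate = doubletRate,
    mitoGeneFraction = mitoGeneFraction,
    targetsPerCircuit = as.integer(targetsPerCircuit),
    circuits = circuits, deGenes = deGenes, seed = as.integer(seed))
}

#' Built-in planted circuits for the default simulated lung
#'
#' One initiating circuit per non-sham treatment, mirroring the kind of
#' sender/ligand/receiver/receptor tuples the pipeline is designed to
#' recover (cytokine genes use mouse symbols for readable reports; nothing
#' downstream depends on the names).
#'
#' @param treatments Treatment labels; circuits are emitted only for
#'   treatments present in this vector.
#' @return A `data.frame` of planted circuits.
#' @export
defaultCircuits <- function(treatments = c("sham", "CNP", "DWCNT", "MWCNT", "LPS")) {
  all <- data.frame(
    treatment = c("CNP", "DWCNT", "MWCNT", "LPS"),
    sender_type = c("AT2", "AM", "Club", "AM"),
    ligand = c("Cxcl1", "Ccl2", "Csf2", "Il1a"),
    receiver_type = c("Lipofibro", "Lipofibro", "AM", "AT2"),
    receptor = c("Cxcr2", "Ccr2", "Csf2ra", "Il1r1"),
    log2_effect = 1.5
  )
  all[all$treatment %in% treatments, , drop = FALSE]
}

#' Ground truth of a simulated perturbation atlas
#'
#' Records every effect planted by [simulateAtlas()]: the circuits
#' (treatment, sender, ligand, receiver, receptor, effect), the full list of
#' planted differentially expressed genes, and the downstream target genes
#' induced in each circuit's receiver cell type (the receiver "gene
#' program" that ligand-activity scoring should trace back to the ligand).
#'
#' @slot circuits `data.frame(treatment, sender_type, ligand, receiver_type,
#'   receptor, log2_effect)`.
#' @slot deGenes `data.frame(treatment, cell_type, gene, log2_effect)`;
#'   includes ligands, receptors and targets of the circuits.
#' @slot targets `data.frame(treatment, ligand, receiver_type, gene)`.
#' @export
setClass("PlantedTruth", representation(
  circuits = "data.frame",
  deGenes = "data.frame",
  targets = "data.frame"
))

setValidity("PlantedTruth", function(object) {
  msg <- character()
  if (nrow(object@circuits) && any(object@circuits$log2_effect == 0))
    msg <- c(msg, "circuit log2_effect must be nonzero")
  if (nrow(object@deGenes) && any(object@deGenes$log2_effect == 0))
    msg <- c(msg, "deGenes log2_effect must be nonzero")
  if (length(msg)) msg else TRUE
})

#' @describeIn PlantedTruth-class planted circuit table.
#' @param truth A `PlantedTruth` object.
#' @export
plantedCircuits <- function(truth) truth@circuits

#' @describeIn PlantedTruth-class planted DE gene table.
#' @export
plantedDEGenes <- function(truth) truth@deGenes

#' @describeIn PlantedTruth-class planted receiver target-gene table.
#' @export
plantedTargets <- function(truth) truth@targets

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", nrow(object@circuits), "circuit(s),",
      nrow(object@deGenes), "planted DE gene(s),",
      nrow(object@targets), "receiver target(s)\n")
  if (nrow(object@circuits)) {
    cat("circuits:\n")
    print(object@circuits, row.names = FALSE)
  }
})

#' Induced cell-cell communication graph for one treatment
#'
#' A directed multigraph over cell types: an edge sender -> receiver is
#' stored for every ligand-receptor pair in which the ligand is
#' differentially upregulated in the sender and the receptor in the
#' receiver. The weight of a (sender, receiver) edge is the number of such
#' pairs.
#'
#' @slot treatment The treatment the connectome was induced by.
#' @slot edges `data.frame(sender, receiver, ligand, receptor)`, one row per
#'   qualifying pair.
#' @slot cellTypes Node universe (all cell types considered).
#' @seealso [inducedConnectome()], [edgeTable()], [asIgraph()]
#' @export
setClass("Connectome", representation(
  treatment = "character",
  edges = "data.frame",
  cellTypes = "character"
))

setValidity("Connectome", function(object) {
  msg <- character()
  need <- c("sender", "receiver", "ligand", "receptor")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, paste("edges needs columns:", paste(need, collapse = ", ")))
  else if (nrow(object@edges)) {
    if (!all(object@edges$sender %in% object@cellTypes) ||
        !all(object@edges$receiver %in% object@cellTypes))
      msg <- c(msg, "edge endpoints must be listed in cellTypes")
    if (anyDuplicated(object@edges[, need]))
      msg <- c(msg, "duplicate (sender, receiver, ligand, receptor) rows")
  }
  if (length(msg) != 1L && length(object@treatment) != 1L)
    msg <- c(msg, "treatment must be a single label")
  if (length(msg)) msg else TRUE
})

#' Aggregated edge table of a connectome
#'
#' @param x A [Connectome-class] object.
#' @return `data.frame(sender, receiver, weight, pairs)` with one row per
#'   directed (sender, receiver) edge; `weight` is the number of qualifying
#'   ligand-receptor pairs and `pairs` a semicolon-separated listing.
#' @export
edgeTable <- function(x) {
  stopifnot(methods::is(x, "Connectome"))
  ed <- x@edges
  if (!nrow(ed)) {
    return(data.frame(sender = character(), receiver = character(),
                      weight = integer(), pairs = character()))
  }
  key <- paste(ed$sender, ed$receiver, sep = "\r")
  spl <- split(seq_len(nrow(ed)), key)
  out <- do.call(rbind, lapply(spl, function(i) {
    data.frame(sender = ed$sender[i[1L]], receiver = ed$receiver[i[1L]],
               weight = length(i),
               pairs = paste(ed$ligand[i], ed$receptor[i], sep = "->",
                             collapse = ";"))
  }))
  rownames(out) <- NULL
  out[order(-out$weight, out$sender, out$receiver), , drop = FALSE]
}

#' Number of distinct directed edges in a connectome
#' @param x A [Connectome-class] object.
#' @export
nEdges <- function(x) nrow(edgeTable(x))

#' Convert a connectome to an igraph object
#'
#' @param x A [Connectome-class] object.
#' @return A directed `igraph` graph whose edge attribute `weight` is the
#'   ligand-receptor pair count and `pairs` the pair listing.
#' @export
asIgraph <- function(x) {
  et <- edgeTable(x)
  igraph::graph_from_data_frame(et, directed = TRUE,
                                vertices = data.frame(name = x@cellTypes))
}

setMethod("show", "Connectome", function(object) {
  et <- edgeTable(object)
  cat("Connectome [", object@treatment, "]: ",
      length(object@cellTypes), " cell types, ",
      nrow(et), " directed edge(s), ",
      nrow(object@edges), " ligand-receptor pair(s)\n", sep = "")
  if (nrow(et)) print(head(et, 10L), row.names = FALSE)
})

#' Marker reference for two-tier cell-type annotation
#'
#' Tier 1 assigns each cluster to a lineage by the lineage's defining gene
#' (canonically *Epcam* for epithelial, *Cldn5* for endothelial, *Col1a2*
#' for stromal, *Ptprc* for immune); tier 2 assigns fine cell types within
#' a lineage by marker gene sets, and a type-to-niche map places each fine
#' type into a major niche.
#'
#' @slot lineageMarkers Named character: lineage -> defining gene. The name
#'   order is the deterministic tie-break order.
#' @slot fineMarkers Named list of character vectors: fine type -> markers.
#' @slot fineLineage Named character: fine type -> lineage.
#' @slot nicheMap Named character: fine type -> niche.
#' @export
setClass("MarkerReference", representation(
  lineageMarkers = "character",
  fineMarkers = "list",
  fineLineage = "character",
  nicheMap = "character"
))

setValidity("MarkerReference", function(object) {
  msg <- character()
  if (is.null(names(object@lineageMarkers)) ||
      anyDuplicated(names(object@lineageMarkers)))
    msg <- c(msg, "lineageMarkers must be uniquely named by lineage")
  ft <- names(object@fineMarkers)
  if (length(object@fineMarkers) &&
      (is.null(ft) || !all(ft %in% names(object@fineLineage))))
    msg <- c(msg, "every fine type needs a lineage in fineLineage")
  if (length(object@fineLineage) &&
      !all(object@fineLineage %in% names(object@lineageMarkers)))
    msg <- c(msg, "fineLineage values must be declared lineages")
  if (length(msg)) msg else TRUE
})

#' Construct a marker reference
#'
#' @param lineageMarkers Named character vector lineage -> defining gene;
#'   the default is the canonical four-lineage lung panel.
#' @param fineMarkers Named list of marker gene sets per fine cell type.
#' @param fineLineage Named character fine type -> lineage.
#' @param nicheMap Named character fine type -> niche label.
#' @return A [MarkerReference-class] object.
#' @export
markerReference <- function(lineageMarkers = c(epithelial = "Epcam",
                                               endothelial = "Cldn5",
                                               stromal = "Col1a2",
                                               immune = "Ptprc"),
                            fineMarkers = list(),
                            fineLineage = character(),
                            nicheMap = character()) {
  methods::new("MarkerReference", lineageMarkers = lineageMarkers,
               fineMarkers = fineMarkers, fineLineage = fineLineage,
               nicheMap = nicheMap)
}

setMethod("show", "MarkerReference", function(object) {
  cat("MarkerReference:", length(object@lineageMarkers), "lineages (",
      paste(names(object@lineageMarkers), object@lineageMarkers,
            sep = ":", collapse = ", "), "),",
      length(object@fineMarkers), "fine types\n")
})

setMethod("show", "SimConfig", function(object) {
  nc <- object@nCellTypes * object@cellsPerSampleType *
    object@samplesPerTreatment * length(object@treatments)
  cat("SimConfig:", object@nCellTypes, "cell types x",
      length(object@treatments), "treatments x",
      object@samplesPerTreatment, "samples =>", nc, "cells,",
      object@nGenes, "genes;", nrow(object@circuits),
      "planted circuit(s), seed", object@seed, "\n")
})
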