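## Simulator for multi-sample, multi-treatment UMI atlases with planted
## cell types, planted treatment-specific cytokine/circuit programs, and
## matched ligand-receptor / regulatory-potential resources.

.lungTypePanel <- data.frame(
  type = c("AT1", "AT2", "Ciliated", "Club", "AM", "Neutrophils",
           "Lipofibro", "gCap"),
  lineage = c("epithelial", "epithelial", "epithelial", "epithelial",
              "immune", "immune", "stromal", "endothelial"),
  niche = c("alveolar epithelium", "alveolar epithelium",
            "airway epithelium", "airway epithelium",
            "monocytes/macrophages", "granulocytes",
            "mesenchyme", "endothelium")
)

.typePanel <- function(n) {
  base <- .lungTypePanel
  if (n <= nrow(base)) return(base[seq_len(n), , drop = FALSE])
  extra <- n - nrow(base)
  lin <- names(c(epithelial = "Epcam", endothelial = "Cldn5",
                 stromal = "Col1a2", immune = "Ptprc"))
  rbind(base, data.frame(
    type = paste0("Type", nrow(base) + seq_len(extra)),
    lineage = lin[(seq_len(extra) - 1L) %% 4L + 1L],
    niche = "other"))
}

#' Simulate a multi-sample perturbation atlas with planted circuits
#'
#' Draws UMI counts from a negative binomial with lognormal per-cell size
#' factors (sd 0.3 on the log scale). Each cell type carries an exclusive
#' block of marker genes at `markerFold` times the base mean, all types of
#' a lineage express that lineage's defining gene (*Epcam*, *Cldn5*,
#' *Col1a2*, *Ptprc*), and a mitochondrial block named with the mouse
#' `mt-` prefix is present so name-based QC works unmodified. Planted
#' circuits multiply the NB mean of the ligand (in the sender type), the
#' receptor and `targetsPerCircuit` downstream target genes (in the
#' receiver type) by `2^log2_effect`, only in cells of the circuit's
#' treatment. The full set of planted effects is returned as ground truth.
#'
#' @param config A [SimConfig-class] object.
#' @return A list with elements
#'   \describe{
#'     \item{sce}{`SingleCellExperiment` (genes x cells) with a `counts`
#'       assay and colData columns `sample_id`, `treatment`, `true_type`,
#'       `true_lineage`, `true_niche`, `is_doublet`.}
#'     \item{truth}{[PlantedTruth-class] listing every planted effect.}
#'     \item{reference}{[MarkerReference-class] matching the planted
#'       marker structure, usable with [annotateTypes()].}
#'   }
#' @details Identical configs (including the seed) give bitwise-identical
#'   output. Configs whose circuits or extra DE genes reference cell types
#'   outside the simulated panel are rejected; referenced gene symbols are
#'   added to the gene universe at a moderately elevated base expression
#'   (twice `baseMean`), emulating constitutively detectable cytokines.
#' @seealso [simConfig()], [injectDoublets()], [makeLRResources()]
#' @export
#' @examples
#' sim <- simulateAtlas(simConfig(nGenes = 300, cellsPerSampleType = 10,
#'                                treatments = c("sham", "CNP"), seed = 7))
#' sim$sce
#' plantedCircuits(sim$truth)
simulateAtlas <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  methods::validObject(config)
  panel <- .typePanel(config@nCellTypes)
  circuits <- config@circuits
  deExtra <- config@deGenes

  badType <- setdiff(c(circuits$sender_type, circuits$receiver_type,
                       deExtra$cell_type), panel$type)
  if (length(badType))
    stop("planted effects reference unknown cell types: ",
         paste(unique(badType), collapse = ", "))
  badTreat <- setdiff(c(circuits$treatment, deExtra$treatment),
                      config@treatments)
  if (length(badTreat))
    stop("planted effects reference unknown treatments: ",
         paste(unique(badTreat), collapse = ", "))

  lineageGenes <- c(epithelial = "Epcam", endothelial = "Cldn5",
                    stromal = "Col1a2", immune = "Ptprc")
  markerGenes <- unlist(lapply(panel$type, function(tp)
    paste0(tp, ".mk", seq_len(config@markerGenesPerType))))
  nMito <- max(1L, round(config@mitoGeneFraction * config@nGenes))
  mitoGenes <- paste0("mt-", seq_len(nMito))
  specialGenes <- setdiff(unique(c(circuits$ligand, circuits$receptor,
                                   deExtra$gene)),
                          c(lineageGenes, markerGenes, mitoGenes))
  nTargets <- nrow(circuits) * config@targetsPerCircuit
  nFixed <- length(lineageGenes) + length(markerGenes) + nMito +
    length(specialGenes)
  nFiller <- config@nGenes - nFixed
  if (nFiller < nTargets + 10L)
    stop("nGenes too small for the requested marker/circuit structure; ",
         "need at least ", nFixed + nTargets + 10L, " genes")
  fillerGenes <- paste0("g", seq_len(nFiller))
  genes <- c(lineageGenes, markerGenes, mitoGenes, specialGenes, fillerGenes)
  names(genes) <- NULL
  stopifnot(!anyDuplicated(genes), length(genes) == config@nGenes)

  withSeed(config@seed, {
    ## baseline expression multiplier per gene
    mult <- rep(1, config@nGenes)
    names(mult) <- genes
    mult[specialGenes] <- 2            # cytokines detectable at baseline
    ## mito block boosted so the expected mito fraction is ~4%
    otherMass <- sum(mult[setdiff(genes, mitoGenes)])
    mult[mitoGenes] <- 0.04 / 0.96 * otherMass / nMito

    ## per-(gene, type) multiplier: lineage genes + exclusive markers
    typeMult <- matrix(1, config@nGenes, nrow(panel),
                       dimnames = list(genes, panel$type))
    for (i in seq_len(nrow(panel))) {
      tp <- panel$type[i]
      typeMult[paste0(tp, ".mk", seq_len(config@markerGenesPerType)), tp] <-
        config@markerFold
      typeMult[lineageGenes[[panel$lineage[i]]], tp] <- config@markerFold
    }

    ## assign circuit target genes from the filler pool (disjoint blocks)
    targetRows <- NULL
    if (nrow(circuits)) {
      pool <- sample(fillerGenes)
      targetRows <- do.call(rbind, lapply(seq_len(nrow(circuits)), function(i) {
        idx <- (i - 1L) * config@targetsPerCircuit +
          seq_len(config@targetsPerCircuit)
        data.frame(treatment = circuits$treatment[i],
                   ligand = circuits$ligand[i],
                   receiver_type = circuits$receiver_type[i],
                   gene = pool[idx])
      }))
    } else {
      targetRows <- data.frame(treatment = character(), ligand = character(),
                               receiver_type = character(), gene = character())
    }

    ## full planted DE table: ligand@sender, receptor@receiver,
    ## targets@receiver, plus any extra user-specified genes
    de <- rbind(
      if (nrow(circuits)) data.frame(treatment = circuits$treatment,
                                     cell_type = circuits$sender_type,
                                     gene = circuits$ligand,
                                     log2_effect = circuits$log2_effect),
      if (nrow(circuits)) data.frame(treatment = circuits$treatment,
                                     cell_type = circuits$receiver_type,
                                     gene = circuits$receptor,
                                     log2_effect = circuits$log2_effect),
      if (nrow(targetRows)) data.frame(
        treatment = targetRows$treatment,
        cell_type = targetRows$receiver_type,
        gene = targetRows$gene,
        log2_effect = circuits$log2_effect[
          match(paste(targetRows$treatment, targetRows$ligand),
                paste(circuits$treatment, circuits$ligand))]),
      deExtra)
    if (is.null(de))
      de <- data.frame(treatment = character(), cell_type = character(),
                       gene = character(), log2_effect = numeric())
    badGene <- setdiff(de$gene, genes)
    if (length(badGene))
      stop("planted effects reference genes outside the simulated universe: ",
           paste(unique(badGene), collapse = ", "))

    ## draw counts block-wise: one block per (treatment, sample, type)
    size <- 1 / config@nbDispersion
    blocks <- expand.grid(type = panel$type,
                          sample = seq_len(config@samplesPerTreatment),
                          treatment = config@treatments,
                          stringsAsFactors = FALSE)
    nc <- config@cellsPerSampleType
    countCols <- vector("list", nrow(blocks))
    metaRows <- vector("list", nrow(blocks))
    for (b in seq_len(nrow(blocks))) {
      tp <- blocks$type[b]; tr <- blocks$treatment[b]; sm <- blocks$sample[b]
      mu <- config@baseMean * mult * typeMult[, tp]
      hit <- de$treatment == tr & de$cell_type == tp
      if (any(hit)) {
        eff <- tapply(de$log2_effect[hit], de$gene[hit], sum)
        mu[names(eff)] <- mu[names(eff)] * 2^eff
      }
      sf <- rlnorm(nc, 0, 0.3)
      m <- matrix(rnbinom(config@nGenes * nc, mu = outer(mu, sf), size = size),
                  config@nGenes, nc)
      countCols[[b]] <- m
      metaRows[[b]] <- data.frame(
        barcode = sprintf("%s_s%d_%s_c%02d", tr, sm, tp, seq_len(nc)),
        sample_id = sprintf("%s_s%d", tr, sm),
        treatment = tr, true_type = tp,
        true_lineage = panel$lineage[match(tp, panel$type)],
        true_niche = panel$niche[match(tp, panel$type)],
        is_doublet = FALSE)
    }
    counts <- Matrix::Matrix(do.call(cbind, countCols), sparse = TRUE)
    meta <- do.call(rbind, metaRows)
    dimnames(counts) <- list(genes, meta$barcode)
    rownames(meta) <- meta$barcode

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(meta[, -1L, drop = FALSE]))

    truth <- methods::new("PlantedTruth", circuits = circuits,
                          deGenes = de, targets = targetRows)
    reference <- markerReference(
      lineageMarkers = lineageGenes,
      fineMarkers = setNames(lapply(panel$type, function(tp)
        paste0(tp, ".mk", seq_len(config@markerGenesPerType))), panel$type),
      fineLineage = setNames(panel$lineage, panel$type),
      nicheMap = setNames(panel$niche, panel$type))

    list(sce = sce, truth = truth, reference = reference)
  })
}

#' Inject artificial doublets into an atlas
#'
#' Appends `round(rate * ncol(sce))` doublets, each the element-wise sum of
#' two distinct parent cells drawn from the same sample (UMI counts are
#' additive, so summing — not averaging — is the physically correct
#' merge). Doublets are flagged in the metadata together with their parent
#' barcodes; `rate = 0` returns the input unchanged.
#'
#' @param sce A `SingleCellExperiment` with a raw `counts` assay.
#' @param rate Doublet fraction relative to the input cell count, in
#'   `[0, 0.5)`.
#' @param seed Integer seed.
#' @return The augmented `SingleCellExperiment`; colData gains
#'   `is_doublet` and `doublet_parents`.
#' @export
injectDoublets <- function(sce, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5) stop("rate must lie in [0, 0.5)")
  if (!"is_doublet" %in% names(SummarizedExperiment::colData(sce)))
    sce$is_doublet <- FALSE
  if (!"doublet_parents" %in% names(SummarizedExperiment::colData(sce)))
    sce$doublet_parents <- NA_character_
  nd <- round(rate * ncol(sce))
  if (nd == 0L) return(sce)
  counts <- .assayCounts(sce)
  cd <- SummarizedExperiment::colData(sce)
  withSeed(seed, {
    samples <- if ("sample_id" %in% names(cd))
      as.character(cd$sample_id) else rep("sample1", ncol(sce))
    bySample <- split(seq_len(ncol(sce)), samples)
    bySample <- bySample[lengths(bySample) >= 2L]
    if (!length(bySample)) stop("no sample with >= 2 cells")
    pick <- sample(names(bySample), nd, replace = TRUE)
    pairs <- t(vapply(pick, function(s) sample(bySample[[s]], 2L),
                      integer(2L)))
    dbl <- counts[, pairs[, 1L], drop = FALSE] +
      counts[, pairs[, 2L], drop = FALSE]
    colnames(dbl) <- sprintf("doublet_%03d", seq_len(nd))
    p1 <- colnames(sce)[pairs[, 1L]]
    p2 <- colnames(sce)[pairs[, 2L]]
    t1 <- if ("true_type" %in% names(cd)) as.character(cd$true_type)[pairs[, 1L]] else NA
    t2 <- if ("true_type" %in% names(cd)) as.character(cd$true_type)[pairs[, 2L]] else NA
    newMeta <- cd[pairs[, 1L], , drop = FALSE]
    rownames(newMeta) <- colnames(dbl)
    newMeta$is_doublet <- TRUE
    newMeta$doublet_parents <- paste(p1, p2, sep = "+")
    if ("true_type" %in% names(cd))
      newMeta$true_type <- paste(t1, t2, sep = "+")
    out <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = cbind(counts, dbl)),
      colData = rbind(cd, newMeta))
    out
  })
}

#' Generate matched ligand-receptor and regulatory-potential resources
#'
#' Builds the two prior-knowledge inputs the circuit-inference stage
#' consumes, consistent with a simulation's planted truth: a
#' ligand-receptor pair table containing every planted (ligand, receptor)
#' pair plus decoy pairs drawn from genes without planted effects, and a
#' ligand x target regulatory-potential matrix in which planted ligands
#' carry high weight (uniform on [0.7, 1]) on their planted downstream
#' targets and low background weight (uniform on [0, 0.3]) elsewhere;
#' decoy ligands carry background weight everywhere.
#'
#' @param truth A [PlantedTruth-class] object.
#' @param genes Character vector: the simulated gene universe.
#' @param nDecoyPairs Number of decoy ligand-receptor pairs.
#' @param nDecoyLigands Number of decoy ligands added to the prior.
#' @param seed Integer seed.
#' @return `list(lrPairs = data.frame(ligand, receptor), regPotential =
#'   matrix)` with ligands as rows and target genes as columns, all
#'   weights in `[0, 1]`.
#' @export
makeLRResources <- function(truth, genes, nDecoyPairs = 50L,
                            nDecoyLigands = 50L, seed = 1L) {
  stopifnot(methods::is(truth, "PlantedTruth"))
  circuits <- truth@circuits
  if (!nrow(circuits) && nDecoyPairs == 0L)
    stop("need planted circuits or decoy pairs")
  nonDE <- setdiff(genes, c(truth@deGenes$gene, circuits$ligand,
                            circuits$receptor))
  nonDE <- grep("^(mt-|Epcam$|Cldn5$|Col1a2$|Ptprc$)", nonDE,
                value = TRUE, invert = TRUE)
  nonDE <- grep("\\.mk", nonDE, value = TRUE, invert = TRUE)
  if (2L * nDecoyPairs + nDecoyLigands > length(nonDE))
    stop("not enough unperturbed genes for the requested decoys")
  withSeed(seed, {
    pool <- sample(nonDE)
    decoyPairs <- if (nDecoyPairs > 0L) {
      data.frame(ligand = pool[seq_len(nDecoyPairs)],
                 receptor = pool[nDecoyPairs + seq_len(nDecoyPairs)])
    } else data.frame(ligand = character(), receptor = character())
    lr <- rbind(unique(circuits[, c("ligand", "receptor")]), decoyPairs)
    rownames(lr) <- NULL

    decoyLigands <- pool[2L * nDecoyPairs + seq_len(nDecoyLigands)]
    ligands <- unique(c(circuits$ligand, decoyPairs$ligand, decoyLigands))
    targets <- setdiff(genes, grep("^mt-", genes, value = TRUE))
    rp <- matrix(runif(length(ligands) * length(targets), 0, 0.3),
                 length(ligands), length(targets),
                 dimnames = list(ligands, targets))
    tg <- truth@targets
    for (i in seq_len(nrow(tg))) {
      if (tg$ligand[i] %in% ligands && tg$gene[i] %in% targets)
        rp[tg$ligand[i], tg$gene[i]] <- runif(1L, 0.7, 1)
    }
    list(lrPairs = lr, regPotential = rp)
  })
}
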