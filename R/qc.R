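## Gene/cell QC cascade, doublet detection and log-normalization.

#' Identify mitochondrial genes by name
#'
#' Case-insensitive `mt-` prefix match (mouse convention), with an
#' optional explicit override list.
#'
#' @param genes Character vector of gene symbols.
#' @param mitoGenes Optional explicit mitochondrial gene list overriding
#'   the prefix rule.
#' @return Logical vector along `genes`.
#' @export
isMitoGene <- function(genes, mitoGenes = NULL) {
  if (!is.null(mitoGenes)) return(genes %in% mitoGenes)
  grepl("^mt-", genes, ignore.case = TRUE)
}

#' Compute per-cell QC metrics
#'
#' Adds `total_counts`, `n_genes_detected` and `mito_fraction` to the
#' column metadata. If no mitochondrial gene is found a warning is issued
#' and `mito_fraction` is set to 0 for all cells.
#'
#' @param sce A `SingleCellExperiment` with a raw `counts` assay.
#' @param mitoGenes Optional explicit mitochondrial gene list; default is
#'   name-based detection via [isMitoGene()].
#' @return The `SingleCellExperiment` with augmented colData.
#' @export
qcMetrics <- function(sce, mitoGenes = NULL) {
  counts <- .assayCounts(sce)
  total <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito <- isMitoGene(rownames(counts), mitoGenes)
  if (!any(mito)) {
    warning("no mitochondrial genes found; mito_fraction set to 0")
    mfrac <- rep(0, ncol(counts))
  } else {
    mfrac <- Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1)
  }
  sce$total_counts <- as.numeric(total)
  sce$n_genes_detected <- as.integer(ngene)
  sce$mito_fraction <- as.numeric(mfrac)
  sce
}

#' Filter genes by minimum count and expressing-cell support
#'
#' Retains genes with total count at least `minCount` (default 1) that are
#' expressed (count > 0) in at least `minCells` cells (default 5); gene
#' order is preserved and no count value is altered.
#'
#' @param sce A `SingleCellExperiment` with a raw `counts` assay.
#' @param minCount Minimum total count across cells.
#' @param minCells Minimum number of expressing cells.
#' @return The gene-filtered `SingleCellExperiment`.
#' @export
#' @examples
#' sim <- simulateAtlas(simConfig(nGenes = 300, cellsPerSampleType = 10,
#'                                treatments = c("sham", "CNP"), seed = 1))
#' dim(filterGenes(sim$sce))
filterGenes <- function(sce, minCount = 1L, minCells = 5L) {
  counts <- .assayCounts(sce)
  keep <- Matrix::rowSums(counts) >= minCount &
    rowExpressingCells(counts) >= minCells
  if (!any(keep)) stop("gene filtering removed every gene; degenerate input")
  sce[keep, ]
}

#' Filter cells by mitochondrial fraction, detected genes and depth
#'
#' Removes cells with mitochondrial fraction greater than or equal to
#' `maxMito` (default 10%), fewer than `minGenes` detected genes (default
#' 300) or fewer than `minCounts` total counts (default 500). Metrics are
#' (re)computed on the current matrix so the call is self-contained;
#' metadata rows stay in sync with the retained barcodes.
#'
#' @inheritParams qcMetrics
#' @param maxMito Cells with `mito_fraction >= maxMito` are removed.
#' @param minGenes Cells with fewer detected genes are removed.
#' @param minCounts Cells with fewer total counts are removed.
#' @return The cell-filtered `SingleCellExperiment`.
#' @export
filterCells <- function(sce, maxMito = 0.10, minGenes = 300L,
                        minCounts = 500L, mitoGenes = NULL) {
  stopifnot(maxMito >= 0, maxMito <= 1)
  sce <- qcMetrics(sce, mitoGenes)
  keep <- sce$mito_fraction < maxMito &
    sce$n_genes_detected >= minGenes &
    sce$total_counts >= minCounts
  if (!any(keep)) stop("cell filtering removed every cell; degenerate input")
  sce[, keep]
}

#' Depth-normalize and log-transform UMI counts
#'
#' With `method = "cp10k"` (default) each cell is scaled to 10,000 total
#' counts before `log1p`; with `method = "none"` the raw counts are
#' `log1p`-transformed directly. The raw `counts` assay is preserved and a
#' `logcounts` assay added.
#'
#' @param sce A `SingleCellExperiment` with a raw `counts` assay.
#' @param method `"cp10k"` or `"none"`.
#' @param scale Target depth for `"cp10k"`.
#' @return The `SingleCellExperiment` with a `logcounts` assay.
#' @export
logNormalize <- function(sce, method = c("cp10k", "none"), scale = 1e4) {
  method <- match.arg(method)
  counts <- methods::as(.assayCounts(sce), "CsparseMatrix")
  total <- Matrix::colSums(counts)
  if (method == "cp10k") {
    if (any(total == 0))
      stop("cells with zero total counts cannot be depth-normalized; ",
           "run filterCells() first")
    norm <- counts %*% Matrix::Diagonal(x = scale / total)
    dimnames(norm) <- dimnames(counts)
  } else {
    norm <- counts
  }
  lg <- norm
  lg@x <- log1p(lg@x)
  SummarizedExperiment::assay(sce, "logcounts") <- lg
  sce
}

#' Scrublet-style doublet scores
#'
#' Simulates `nSim` synthetic doublets by summing the raw counts of random
#' observed cell pairs, embeds observed and simulated cells jointly in PCA
#' space of the log-normalized pooled matrix, and scores every observed
#' cell by the fraction `f` of its k nearest neighbours that are simulated
#' doublets. The fraction is rescaled for the simulation ratio
#' `r = nSim / (nObs + nSim)` and the expected doublet rate `rho` into the
#' posterior-style score
#' `(f/r) rho / ((f/r) rho + ((1-f)/(1-r)) (1-rho))`, which lies in
#' `[0, 1]`, equals `rho` when a cell's neighbourhood is exactly
#' ratio-neutral (as in a homogeneous population, where doublets are
#' indistinguishable), and approaches 1 for neotypic doublets surrounded
#' by simulated ones.
#'
#' @param sce A `SingleCellExperiment` (post gene/cell filtering) with a
#'   raw `counts` assay.
#' @param nSim Number of simulated doublets; default twice the number of
#'   observed cells (the neighbourhood is expanded by the simulation
#'   ratio so the effective observed-cell neighbourhood stays `k`).
#' @param k Neighbourhood size; default `round(0.5 * sqrt(n_cells))`.
#' @param nPCs Number of principal components (default 30).
#' @param expectedRate Prior expected doublet rate `rho` (default 0.1).
#' @param seed Integer seed.
#' @return Numeric vector of doublet scores, one per observed cell.
#' @seealso [doubletThreshold()]
#' @export
detectDoublets <- function(sce, nSim = 2L * ncol(sce), k = NULL, nPCs = 30L,
                           expectedRate = 0.1, seed = 1L) {
  counts <- .assayCounts(sce)
  nObs <- ncol(counts)
  if (is.null(k)) k <- max(3L, round(0.5 * sqrt(nObs)))
  if (k >= nObs) stop("k must be smaller than the number of cells")
  withSeed(seed, {
    p1 <- sample.int(nObs, nSim, replace = TRUE)
    p2 <- sample.int(nObs, nSim, replace = TRUE)
    swap <- p1 == p2
    p2[swap] <- (p2[swap] %% nObs) + 1L
    simCounts <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
    pooled <- cbind(counts, simCounts)
    total <- Matrix::colSums(pooled)
    norm <- pooled %*% Matrix::Diagonal(x = 1e4 / pmax(total, 1))
    norm@x <- log1p(norm@x)
    X <- as.matrix(Matrix::t(norm))
    nPCs <- min(nPCs, ncol(X) - 1L, nrow(X) - 1L)
    pcs <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nPCs)$x
    ## expand the neighbourhood by the simulation ratio so that the
    ## effective number of observed-cell neighbours stays ~k
    kAdj <- round(k * (1 + nSim / nObs))
    nn <- knnIndices(pcs, kAdj)
    k <- kAdj
    isSim <- c(rep(FALSE, nObs), rep(TRUE, nSim))
    fAll <- rowMeans(matrix(isSim[nn], nrow(nn), k))
    r <- nSim / (nObs + nSim)
    rho <- expectedRate
    rescale <- function(f)
      (f / r) * rho / ((f / r) * rho + ((1 - f) / (1 - r)) * (1 - rho))
    score <- rescale(fAll[seq_len(nObs)])
    ## simulated doublets' own scores, kept for threshold estimation
    ss <- rescale(fAll[nObs + seq_len(nSim)])
    attr(score, "simScores") <- ss
    names(score) <- colnames(counts)
    score
  })
}

#' Automatic doublet-score threshold
#'
#' Takes the minimum-density valley between the lowest and highest
#' prominent modes (local maxima reaching at least 5% of the peak
#' density) of the observed cells' score distribution — singlets form the
#' dominant low mode and neotypic doublets the high mode(s). If the
#' distribution has a single prominent mode (as in doublet-free
#' homogeneous data), the fixed fallback 0.25 is returned.
#'
#' @param scores Doublet scores from [detectDoublets()].
#' @param fallback Threshold used when no valley is found.
#' @return A single numeric threshold.
#' @export
doubletThreshold <- function(scores, fallback = 0.25) {
  x <- as.numeric(scores[is.finite(scores)])
  if (length(unique(x)) < 3L) return(fallback)
  d <- density(x, n = 512)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] >= 0.05 * max(y)]   # prominent modes only
  if (length(locmax) < 2L) return(fallback)
  lo <- min(locmax); hi <- max(locmax)
  valley <- lo + which.min(y[lo:hi]) - 1L
  d$x[valley]
}
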