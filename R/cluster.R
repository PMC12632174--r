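## Consensus HVG selection, PCA/kNN embedding, Leiden clustering,
## Wilcoxon marker detection and two-tier cell-type annotation.

#' Per-sample consensus highly variable genes
#'
#' Computes dispersion-based HVGs independently for every sample
#' (normalized-dispersion binning on the de-logged values: genes are
#' binned by mean expression and the variance/mean dispersion is z-scored
#' within each bin) and keeps as consensus the genes flagged HVG in at
#' least two samples.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay.
#' @param nTop HVGs per sample.
#' @param sampleCol colData column holding the sample identifier.
#' @param nBins Number of mean-expression bins.
#' @return A list with `perSample` (named list of per-sample HVG vectors),
#'   `consensus` (character vector), and `nFlagged` (per-gene flag counts).
#' @export
consensusHVGs <- function(sce, nTop = 2000L, sampleCol = "sample_id",
                          nBins = 20L) {
  X <- .assayLogcounts(sce)
  samples <- as.character(SummarizedExperiment::colData(sce)[[sampleCol]])
  if (length(unique(samples)) < 2L)
    stop("consensus HVG selection needs at least 2 samples")
  perSample <- lapply(split(seq_len(ncol(X)), samples), function(idx) {
    hvgSingle(X[, idx, drop = FALSE], nTop = nTop, nBins = nBins)
  })
  flags <- table(unlist(perSample))
  consensus <- names(flags)[flags >= 2L]
  consensus <- consensus[order(match(consensus, rownames(X)))]
  list(perSample = perSample, consensus = consensus,
       nFlagged = flags)
}

## Seurat-flavoured HVGs for one expression block (genes x cells, log1p).
hvgSingle <- function(X, nTop = 2000L, nBins = 20L) {
  E <- expm1(X)
  m <- Matrix::rowMeans(E)
  v <- Matrix::rowMeans(E^2) - m^2
  v <- v * ncol(E) / max(1L, ncol(E) - 1L)
  v[v < 1e-8 * pmax(m^2, 1e-12)] <- 0     # strip FP cancellation noise
  disp <- ifelse(m > 0, v / m, 0)
  expressed <- m > 0 & disp > 0
  if (!any(expressed)) return(character())
  bins <- cut(rank(m[expressed], ties.method = "first"),
              breaks = nBins, labels = FALSE)
  z <- disp[expressed]
  for (b in unique(bins)) {
    i <- bins == b
    mu <- mean(z[i]); s <- sd(z[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (z[i] - mu) / s
  }
  genes <- rownames(X)[expressed]
  genes[order(z, decreasing = TRUE)][seq_len(min(nTop, length(genes)))]
}

#' PCA embedding and symmetric kNN graph
#'
#' Scales the log-normalized values of the supplied genes to zero mean and
#' unit variance per gene (values clipped at 10), computes principal
#' components, and builds the symmetric (union) k-nearest-neighbour graph
#' in PC space.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay.
#' @param genes Genes to embed on (typically the consensus HVGs).
#' @param nPCs Number of principal components (default 50; reduced to the
#'   available rank on small inputs).
#' @param k Neighbourhood size.
#' @return A list with `pcs` (cells x PCs matrix) and `graph` (undirected
#'   `igraph` graph with one vertex per cell).
#' @export
embedGraph <- function(sce, genes, nPCs = 50L, k = 15L) {
  X <- .assayLogcounts(sce)
  genes <- intersect(genes, rownames(X))
  if (!length(genes)) stop("none of the requested genes are present")
  if (k >= ncol(X)) stop("fewer cells than requested neighbours")
  M <- t(as.matrix(X[genes, , drop = FALSE]))
  M <- scale(M)
  M[is.na(M)] <- 0
  M[M > 10] <- 10
  nPCs <- min(nPCs, ncol(M), nrow(M) - 1L)
  pcs <- prcomp(M, center = FALSE, scale. = FALSE, rank. = nPCs)$x
  rownames(pcs) <- colnames(X)
  nn <- knnIndices(pcs, k)
  edges <- cbind(rep(seq_len(nrow(nn)), k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- colnames(X)
  list(pcs = pcs, graph = g)
}

#' Leiden community detection
#'
#' @param graph An `igraph` graph (e.g. from [embedGraph()]).
#' @param resolution Resolution parameter (modularity objective).
#' @param seed Integer seed; identical seeds give identical labels.
#' @param nIterations Leiden refinement iterations.
#' @return Factor of cluster labels, named by vertex name.
#' @export
clusterLeiden <- function(graph, resolution = 1, seed = 1L,
                          nIterations = 5L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  withSeed(seed, {
    args <- list(graph, objective_function = "modularity",
                 n_iterations = nIterations)
    if ("resolution" %in% names(formals(igraph::cluster_leiden))) {
      args$resolution <- resolution
    } else {
      args$resolution_parameter <- resolution
    }
    cl <- do.call(igraph::cluster_leiden, args)
    setNames(factor(igraph::membership(cl)), igraph::V(graph)$name)
  })
}

## Wilcoxon rank-sum p-values for every gene, one group vs the rest.
## `ranks` are precomputed row ranks over all cells; exact tail via
## stats::pwilcox when both groups are small and the gene has no ties,
## normal approximation with tie correction otherwise.
.wilcoxonRows <- function(ranks, tieTerm, inGroup, nTies) {
  n1 <- sum(inGroup); n2 <- sum(!inGroup); n <- n1 + n2
  R1 <- rowSums(ranks[, inGroup, drop = FALSE])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- (n1 * n2 / 12) * ((n + 1) - tieTerm / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (U - mu) / sqrt(sig2), 0)
  p <- 2 * pnorm(-abs(z))
  exact <- n1 < 50 && n2 < 50
  if (exact) {
    noTies <- nTies == 0
    if (any(noTies)) {
      Ue <- U[noTies]
      pe <- ifelse(Ue > mu,
                   2 * pwilcox(Ue - 1, n1, n2, lower.tail = FALSE),
                   2 * pwilcox(Ue, n1, n2))
      p[noTies] <- pmin(pe, 1)
    }
  }
  list(U = U, z = z, p = pmin(p, 1))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test used for marker detection: exact two-sided p-value for
#' small tie-free samples (via the exact rank-sum distribution), normal
#' approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors.
#' @return A list with `statistic` (the Mann-Whitney U of `x`) and `p`.
#' @export
#' @examples
#' wilcoxonTest(c(1, 2, 3), c(4, 5, 6))$p  # exact: 2/20
wilcoxonTest <- function(x, y) {
  v <- c(x, y)
  r <- rank(v)
  tt <- table(v)
  res <- .wilcoxonRows(matrix(r, 1L), sum(tt^3 - tt),
                       seq_along(v) <= length(x), sum(tt > 1))
  list(statistic = unname(res$U), p = unname(res$p))
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For every cluster, tests each gene's log-normalized expression in the
#' cluster against all remaining cells, adjusts p-values by
#' Benjamini-Hochberg within the cluster contrast, and flags markers with
#' `q < fdr` and `log2FC > lfc` (both required). log2 fold changes are
#' computed on de-logged group means with a 1e-9 pseudocount.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay.
#' @param labels Cluster labels, one per cell.
#' @param fdr,lfc Marker thresholds (defaults 0.05 and 0.5).
#' @param topN Per-cluster rank cutoff retained in the output (default 500,
#'   mirroring top-500 marker exports); set `Inf` to keep all genes.
#' @return `data.frame(cluster, gene, log2FC, statistic, p, q, rank,
#'   is_marker)`, ranks ordered by the test statistic within each cluster.
#' @export
rankMarkers <- function(sce, labels, fdr = 0.05, lfc = 0.5, topN = 500L) {
  X <- .assayLogcounts(sce)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(X))
  Xd <- as.matrix(X)
  ranks <- t(apply(Xd, 1L, rank))
  tieStats <- apply(Xd, 1L, function(v) {
    tt <- table(v)
    c(sum(tt^3 - tt), sum(tt > 1))
  })
  E <- expm1(Xd)
  out <- lapply(sort(unique(labels)), function(cl) {
    inG <- labels == cl
    if (sum(inG) < 2L) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      return(NULL)
    }
    w <- .wilcoxonRows(ranks, tieStats[1L, ], inG, tieStats[2L, ])
    lfcv <- log2((rowMeans(E[, inG, drop = FALSE]) + 1e-9) /
                 (rowMeans(E[, !inG, drop = FALSE]) + 1e-9))
    q <- p.adjust(w$p, method = "BH")
    ord <- order(w$z, decreasing = TRUE)
    df <- data.frame(cluster = cl, gene = rownames(Xd), log2FC = lfcv,
                     statistic = w$z, p = w$p, q = q,
                     is_marker = q < fdr & lfcv > lfc)
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    df[df$rank <= topN, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-tier cell-type annotation
#'
#' Tier 1 assigns every cluster the lineage whose defining gene has the
#' highest mean log-normalized expression in the cluster (exact ties break
#' deterministically by the lineage order declared in the reference).
#' Tier 2 repeats HVG selection, PCA/kNN embedding and Leiden clustering
#' within each lineage and labels each subcluster with the fine cell type
#' whose marker set has the highest mean expression; the niche label is
#' taken from the reference's type-to-niche map. Tier-2 labels never cross
#' lineage boundaries by construction.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay and a
#'   `sample_id` colData column.
#' @param clusters Tier-1 cluster labels, one per cell.
#' @param reference A [MarkerReference-class].
#' @param resolution Tier-2 Leiden resolution (default 0.8).
#' @param nTop,k,nPCs Tier-2 HVG/embedding parameters.
#' @param seed Integer seed.
#' @return The `SingleCellExperiment` with colData columns `cluster`,
#'   `lineage`, `cell_type` and `niche`.
#' @export
annotateTypes <- function(sce, clusters, reference, resolution = 0.8,
                          nTop = 2000L, k = 15L, nPCs = 50L, seed = 1L) {
  stopifnot(methods::is(reference, "MarkerReference"))
  X <- .assayLogcounts(sce)
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(X))
  lm <- reference@lineageMarkers
  missing <- setdiff(lm, rownames(X))
  if (length(missing))
    stop("lineage-defining genes absent from the matrix: ",
         paste(missing, collapse = ", "),
         " (lineages ", paste(names(lm)[lm %in% missing], collapse = ", "),
         " unassignable)")
  ## tier 1: lineage per cluster by defining-gene mean; which.max breaks
  ## exact ties by the declared lineage order
  lineage <- setNames(rep(NA_character_, length(unique(clusters))),
                      sort(unique(clusters)))
  for (cl in names(lineage)) {
    mns <- vapply(lm, function(g)
      mean(X[g, clusters == cl, drop = TRUE]), numeric(1L))
    lineage[cl] <- names(lm)[which.max(mns)]
  }
  cellLineage <- unname(lineage[clusters])

  ## tier 2: recluster within each lineage and match fine marker sets
  cellType <- cellLineage
  for (lin in unique(cellLineage)) {
    idx <- which(cellLineage == lin)
    cand <- names(reference@fineLineage)[reference@fineLineage == lin]
    cand <- cand[cand %in% names(reference@fineMarkers)]
    if (!length(cand)) next
    sub <- sce[, idx]
    subLabels <- tryCatch({
      hv <- consensusHVGs(sub, nTop = nTop)
      eg <- embedGraph(sub, hv$consensus, nPCs = nPCs,
                       k = min(k, ncol(sub) - 1L))
      clusterLeiden(eg$graph, resolution = resolution,
                    seed = stageSeed(seed, paste0("tier2-", lin)))
    }, error = function(e) factor(rep(1L, length(idx))))
    for (sc in levels(subLabels)) {
      cells <- idx[subLabels == sc]
      score <- vapply(cand, function(ft) {
        gs <- intersect(reference@fineMarkers[[ft]], rownames(X))
        if (!length(gs)) return(-Inf)
        sub <- X[gs, cells, drop = FALSE]
        sum(sub) / (length(gs) * length(cells))
      }, numeric(1L))
      cellType[cells] <- cand[which.max(score)]
    }
  }
  niche <- unname(reference@nicheMap[cellType])
  sce$cluster <- clusters
  sce$lineage <- cellLineage
  sce$cell_type <- cellType
  sce$niche <- niche
  sce
}
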