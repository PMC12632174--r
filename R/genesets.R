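## Gene-signature scoring, GSVA-style single-sample enrichment, preranked
## GSEA, and dot-plot statistics.

#' Expression-matched gene-signature score
#'
#' Per-cell score of a gene set: mean log-normalized expression of the set
#' minus the mean of a control pool sampled from expression-matched bins
#' (genes are binned into `nBins` equal-frequency bins by average
#' expression; `ctrlSize` control genes are drawn from the bin of every
#' set gene). A set equal to the whole universe scores exactly 0, and the
#' score is invariant to adding a constant to every gene in every cell.
#'
#' @param sce A `SingleCellExperiment` with a `logcounts` assay.
#' @param geneSet Character vector of gene symbols.
#' @param nBins Number of expression bins (default 25).
#' @param ctrlSize Control genes sampled per set gene (default 50).
#' @param seed Integer seed for the control-pool draw.
#' @return Named numeric vector of per-cell scores.
#' @export
scoreGeneSet <- function(sce, geneSet, nBins = 25L, ctrlSize = 50L,
                         seed = 1L) {
  X <- .assayLogcounts(sce)
  geneSet <- intersect(unique(geneSet), rownames(X))
  if (!length(geneSet))
    stop("gene set has empty intersection with the gene universe")
  avg <- Matrix::rowMeans(X)
  n <- length(avg)
  bin <- ceiling(rank(avg, ties.method = "first") / (n / nBins))
  names(bin) <- rownames(X)
  withSeed(seed, {
    ctrl <- unique(unlist(lapply(geneSet, function(g) {
      members <- names(bin)[bin == bin[[g]]]
      sample(members, min(ctrlSize, length(members)))
    })))
    ctrl <- setdiff(ctrl, geneSet)
    setScore <- Matrix::colMeans(X[geneSet, , drop = FALSE])
    ctrlScore <- if (length(ctrl)) {
      Matrix::colMeans(X[ctrl, , drop = FALSE])
    } else setScore
    setNames(as.numeric(setScore - ctrlScore), colnames(X))
  })
}

## Kernel-smoothed cumulative density per gene across samples.
.kcdf <- function(expr, kernel) {
  t(vapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ]
    if (kernel == "gaussian") {
      h <- sd(x) / 4
      if (!is.finite(h) || h == 0) return(rep(0.5, length(x)))
      rowMeans(pnorm(outer(x, x, "-") / h))
    } else {
      rowMeans(vapply(x, function(m) stats::ppois(x, m + 0.5),
                      numeric(length(x))))
    }
  }, numeric(ncol(expr))))
}

#' GSVA-style single-sample gene-set scores
#'
#' Gene Set Variation Analysis scores: a kernel-smoothed ECDF is estimated
#' per gene across samples (Gaussian kernel with bandwidth sd/4 for
#' log-scale data; Poisson kernel for raw counts), converted to per-sample
#' gene ranks, symmetrized about the middle rank, and a weighted
#' Kolmogorov-Smirnov random walk is run down each sample's ranked list.
#' The default `"maxdiff"` convention reports the sum of the maximum
#' positive and maximum negative deviation; `"absmax"` reports the single
#' deviation of largest magnitude.
#'
#' @param expr Numeric matrix, genes x samples (at least 2 samples; GSVA
#'   scores are relative across samples).
#' @param sets Named list of gene sets.
#' @param kernel `"gaussian"` (log-normalized input) or `"poisson"`
#'   (raw counts).
#' @param tau Weighting exponent of the rank statistic (default 1).
#' @param method `"maxdiff"` or `"absmax"`.
#' @return Numeric matrix, sets x samples.
#' @export
gsvaScores <- function(expr, sets, kernel = c("gaussian", "poisson"),
                       tau = 1, method = c("maxdiff", "absmax")) {
  kernel <- match.arg(kernel)
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("GSVA needs at least 2 samples")
  if (is.null(names(sets))) stop("sets must be named")
  p <- nrow(expr)
  z <- .kcdf(expr, kernel)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  ## per-sample decreasing order and symmetrized rank statistic
  for (j in seq_len(ncol(expr))) {
    ord <- order(z[, j], decreasing = TRUE)
    rk <- integer(p); rk[ord] <- seq_len(p)
    s <- abs(p / 2 - rk)
    for (k in seq_along(sets)) {
      setIdx <- which(rownames(expr) %in% sets[[k]])
      if (!length(setIdx))
        stop("set '", names(sets)[k], "' does not intersect the universe")
      inSet <- logical(p); inSet[setIdx] <- TRUE
      inSetOrd <- inSet[ord]
      w <- s[ord]^tau
      stepHit <- ifelse(inSetOrd, w, 0)
      denom <- sum(stepHit)
      nMiss <- p - length(setIdx)
      dev <- cumsum(stepHit / denom - ifelse(inSetOrd, 0, 1 / nMiss))
      out[k, j] <- if (method == "maxdiff") {
        max(dev, 0) + min(dev, 0)
      } else {
        dev[which.max(abs(dev))]
      }
    }
  }
  out
}

## Enrichment score from sorted hit positions. `posMat` is nPerm x s with
## rows sorted increasing; `absw` the |stat|^p weights in ranked order.
.esFromPositions <- function(posMat, absw, N) {
  s <- ncol(posMat)
  W <- matrix(absw[posMat], nrow(posMat), s)
  CH <- t(apply(W, 1L, cumsum)) / rowSums(W)
  miss <- sweep(posMat, 2L, seq_len(s)) / (N - s)
  devAfter <- CH - miss
  devBefore <- cbind(0, CH[, -s, drop = FALSE]) - miss
  hi <- apply(devAfter, 1L, max)
  lo <- apply(devBefore, 1L, min)
  ifelse(hi >= -lo, hi, lo)
}

#' Preranked GSEA with gene-label permutations
#'
#' Weighted Kolmogorov-Smirnov enrichment score on a ranked gene list
#' (hits advance by `|stat|^weightP` normalized to the set total, misses
#' retreat by `1/(N - |S|)`; the ES is the running-sum deviation of
#' largest magnitude). The p-value is the fraction of `nPerm` random
#' same-size gene sets whose |ES| reaches the observed |ES| (with the
#' usual +1 correction); NES divides the ES by the mean |ES| of the
#' permutations in the matching sign class; q is BH across the supplied
#' sets.
#'
#' @param ranking Named numeric vector (e.g. log2 fold changes from a DGE
#'   contrast); must contain no NA.
#' @param sets Named list of gene sets (or a single character vector).
#' @param weightP Weighting exponent (default 1; 0 gives the classical
#'   unweighted KS statistic).
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return `data.frame(gene_set, size, ES, NES, p, q)`.
#' @export
gseaPreranked <- function(ranking, sets, weightP = 1, nPerm = 1000L,
                          seed = 1L) {
  if (anyNA(ranking)) stop("ranking contains NA")
  if (!is.list(sets)) sets <- list(set = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  ord <- order(ranking, decreasing = TRUE)
  rankedGenes <- names(ranking)[ord]
  absw <- abs(ranking[ord])^weightP
  N <- length(ranking)
  withSeed(seed, {
    rows <- lapply(names(sets), function(nm) {
      pos <- sort(match(intersect(sets[[nm]], rankedGenes), rankedGenes))
      sz <- length(pos)
      if (sz < 2L)
        return(data.frame(gene_set = nm, size = sz, ES = NA_real_,
                          NES = NA_real_, p = NA_real_))
      if (sz > N / 2)
        warning("set '", nm, "' covers more than half the universe")
      es <- .esFromPositions(matrix(pos, 1L), absw, N)
      permPos <- t(vapply(seq_len(nPerm),
                          function(i) sort(sample.int(N, sz)),
                          integer(sz)))
      esPerm <- .esFromPositions(permPos, absw, N)
      p <- (1 + sum(abs(esPerm) >= abs(es))) / (nPerm + 1)
      sameSign <- abs(esPerm[sign(esPerm) == sign(es)])
      nes <- if (length(sameSign)) es / mean(sameSign) else NA_real_
      data.frame(gene_set = nm, size = sz, ES = es, NES = nes, p = p)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
  })
}

#' Fraction-expressing and mean-expression statistics
#'
#' The numeric substrate of dot/matrix plots: for every
#' (cell type, treatment, gene), the fraction of cells with a positive
#' raw count and the mean log-normalized expression.
#'
#' @param sce A `SingleCellExperiment` with `counts` and `logcounts`
#'   assays and colData columns `treatment` and `typeCol`.
#' @param genes Genes of interest; unknown names raise an error listing
#'   them.
#' @param typeCol colData column holding the cell-type label.
#' @return `data.frame(cell_type, treatment, gene, fraction_expressing,
#'   mean_expression)`.
#' @export
dotplotStats <- function(sce, genes, typeCol = "cell_type") {
  counts <- .assayCounts(sce)
  X <- .assayLogcounts(sce)
  unknown <- setdiff(genes, rownames(counts))
  if (length(unknown))
    stop("unknown gene names: ", paste(unknown, collapse = ", "))
  cd <- SummarizedExperiment::colData(sce)
  grp <- interaction(as.character(cd[[typeCol]]),
                     as.character(cd$treatment), drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    data.frame(
      cell_type = parts[1L], treatment = parts[2L], gene = genes,
      fraction_expressing = as.numeric(
        Matrix::rowMeans(counts[genes, idx, drop = FALSE] > 0)),
      mean_expression = as.numeric(
        Matrix::rowMeans(X[genes, idx, drop = FALSE])))
  }))
  rownames(out) <- NULL
  out
}
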