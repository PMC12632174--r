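## Per-cell-type treatment-vs-sham differential expression: Welch's t
## test, BH correction per contrast, and the effect-size summary.

#' Welch's two-sample t test
#'
#' Direct implementation of the Welch statistic
#' \eqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution. When both sample variances are zero the test is
#' degenerate: `p = 1` if the means are equal, otherwise `p = 0` with
#' `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with `statistic`, `df`, `p` and `degenerate`.
#' @export
#' @examples
#' welchTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
welchTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  d <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_, p = if (d == 0) 1 else 0,
                degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

## Vectorized Welch test over matrix rows: X (genes x n1) vs Y (genes x n2).
rowWelch <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- Matrix::rowMeans(X); my <- Matrix::rowMeans(Y)
  vx <- (Matrix::rowMeans(X^2) - mx^2) * nx / (nx - 1)
  vy <- (Matrix::rowMeans(Y^2) - my^2) * ny / (ny - 1)
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)
  se2 <- vx / nx + vy / ny
  d <- mx - my
  t <- ifelse(se2 > 0, d / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df), ifelse(d == 0, 1, 0))
  t[se2 == 0 & d != 0] <- sign(d[se2 == 0 & d != 0]) * Inf
  list(statistic = t, df = df, p = p, meanX = mx, meanY = my)
}

#' Per-cell-type differential expression against pooled sham
#'
#' For every cell type and every non-sham treatment, tests each gene that
#' is expressed (raw count > 0) in at least `minCellsExpressing` cells of
#' the two compared groups combined, using Welch's t test on the
#' log-normalized values. P-values are BH-adjusted within each
#' (cell type, treatment) contrast; `direction` is `"up"` when
#' `q < fdr` and `log2FC > lfcUp`, `"down"` when `q < fdr` and
#' `log2FC < lfcDown`, `"ns"` otherwise. Cell types with fewer than
#' `minGroup` cells in either group are skipped with a warning.
#'
#' @param sce A `SingleCellExperiment` with `counts` and `logcounts`
#'   assays and colData columns `treatment` and `typeCol`.
#' @param typeCol colData column holding the cell-type label.
#' @param minCellsExpressing Minimum expressing cells across the two
#'   groups combined (default 10).
#' @param lfcUp,lfcDown,fdr Direction thresholds (defaults 0.5, -0.5, 0.05).
#' @param sham Label of the control condition.
#' @param minGroup Minimum cells per group (default 3).
#' @return `data.frame(cell_type, treatment, gene, mean_treat, mean_sham,
#'   log2FC, t_statistic, df_welch, p, q, n_cells_expressing, direction)`.
#' @export
dgePerCellType <- function(sce, typeCol = "cell_type",
                           minCellsExpressing = 10L,
                           lfcUp = 0.5, lfcDown = -0.5, fdr = 0.05,
                           sham = "sham", minGroup = 3L) {
  stopifnot(lfcUp > 0, lfcDown < 0, fdr > 0, fdr < 1)
  counts <- .assayCounts(sce)
  X <- .assayLogcounts(sce)
  cd <- SummarizedExperiment::colData(sce)
  types <- as.character(cd[[typeCol]])
  treat <- as.character(cd$treatment)
  if (!sham %in% treat) stop("no cells with treatment '", sham, "'")
  res <- list()
  for (tp in sort(unique(types))) {
    shamIdx <- which(types == tp & treat == sham)
    for (tr in setdiff(sort(unique(treat)), sham)) {
      trIdx <- which(types == tp & treat == tr)
      if (length(trIdx) < minGroup || length(shamIdx) < minGroup) {
        warning("skipping ", tp, " / ", tr, ": fewer than ", minGroup,
                " cells in a group")
        next
      }
      nExpr <- rowExpressingCells(counts[, c(trIdx, shamIdx), drop = FALSE])
      tested <- nExpr >= minCellsExpressing
      if (!any(tested)) next
      Xt <- X[tested, trIdx, drop = FALSE]
      Xs <- X[tested, shamIdx, drop = FALSE]
      w <- rowWelch(Xt, Xs)
      lfc <- rowLog2FC(Xt, Xs)
      q <- p.adjust(w$p, method = "BH")
      dir <- ifelse(q < fdr & lfc > lfcUp, "up",
                    ifelse(q < fdr & lfc < lfcDown, "down", "ns"))
      res[[paste(tp, tr)]] <- data.frame(
        cell_type = tp, treatment = tr, gene = rownames(X)[tested],
        mean_treat = w$meanX, mean_sham = w$meanY, log2FC = lfc,
        t_statistic = w$statistic, df_welch = w$df, p = w$p, q = q,
        n_cells_expressing = nExpr[tested], direction = dir)
    }
  }
  if (!length(res))
    return(data.frame(cell_type = character(), treatment = character(),
                      gene = character(), mean_treat = numeric(),
                      mean_sham = numeric(), log2FC = numeric(),
                      t_statistic = numeric(), df_welch = numeric(),
                      p = numeric(), q = numeric(),
                      n_cells_expressing = integer(),
                      direction = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Up/down regulated gene counts per cell type and treatment
#'
#' The numeric substrate of an effect-size heatmap: the number of
#' significantly up- and downregulated genes for every
#' (cell type, treatment) contrast in a DGE table.
#'
#' @param dge A DGE table from [dgePerCellType()].
#' @return `data.frame(cell_type, treatment, n_up, n_down)`; empty input
#'   gives a zero-row frame.
#' @export
effectSizeSummary <- function(dge) {
  if (!nrow(dge))
    return(data.frame(cell_type = character(), treatment = character(),
                      n_up = integer(), n_down = integer()))
  key <- interaction(dge$cell_type, dge$treatment, drop = TRUE, sep = "\r")
  spl <- split(dge$direction, key)
  out <- do.call(rbind, lapply(names(spl), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(cell_type = parts[1L], treatment = parts[2L],
               n_up = sum(spl[[k]] == "up"),
               n_down = sum(spl[[k]] == "down"))
  }))
  out[order(out$cell_type, out$treatment), , drop = FALSE]
}
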