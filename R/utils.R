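#' @import methods
#' @importFrom stats cor density dist p.adjust prcomp pnorm pt pwilcox rnbinom
#'   rlnorm runif rbinom sd setNames var aggregate quantile binom.test ks.test
#' @importFrom utils head read.delim write.table
NULL

## Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Derive a per-stage seed from a global seed
#'
#' Expands one global seed into reproducible per-stage seeds by hashing the
#' stage name, so that pipeline stages are independently re-runnable with
#' identical random streams.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stageSeed(1L, "qc") != stageSeed(1L, "dge")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

## log2 fold change of de-logged group means with a small pseudocount,
## the common scRNA-seq convention on log1p-normalized data.
log2FCMeans <- function(x, y, pseudo = 1e-9) {
  log2((mean(expm1(x)) + pseudo) / (mean(expm1(y)) + pseudo))
}

## Row-wise variant for matrices (genes x cells).
rowLog2FC <- function(X, Y, pseudo = 1e-9) {
  mx <- Matrix::rowMeans(expm1(X))
  my <- Matrix::rowMeans(expm1(Y))
  log2((mx + pseudo) / (my + pseudo))
}

## Number of cells with a positive raw count, per gene.
rowExpressingCells <- function(counts) {
  as.integer(Matrix::rowSums(counts > 0))
}

.assayCounts <- function(sce) {
  stopifnot(methods::is(sce, "SummarizedExperiment"))
  if (!"counts" %in% SummarizedExperiment::assayNames(sce))
    stop("no 'counts' assay present")
  SummarizedExperiment::assay(sce, "counts")
}

.assayLogcounts <- function(sce) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    stop("no 'logcounts' assay present; run logNormalize() first")
  SummarizedExperiment::assay(sce, "logcounts")
}

## Euclidean k nearest neighbours among the rows of `x` (n x d), optionally
## for query rows `q`. Returns an n_q x k matrix of row indices into `x`.
## Dense crossprod trick; fine for the few thousand cells this package targets.
knnIndices <- function(x, k, query = NULL) {
  self <- is.null(query)
  if (self) query <- x
  if (k >= nrow(x) + ifelse(self, 0L, 1L))
    stop("k must be smaller than the number of reference points")
  x2 <- rowSums(x^2)
  q2 <- rowSums(query^2)
  nn <- matrix(0L, nrow(query), k)
  chunk <- max(1L, floor(2e7 / nrow(x)))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    d2 <- outer(q2[idx], x2, "+") - 2 * tcrossprod(query[idx, , drop = FALSE], x)
    if (self) d2[cbind(seq_along(idx), idx)] <- Inf
    nn[idx, ] <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  }
  nn
}
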