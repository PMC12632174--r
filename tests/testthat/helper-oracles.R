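## Independent straight-line oracles shared across test files.

## Literal, loop-based GSVA recipe (kernel ECDF -> symmetric ranks ->
## random walk, maxdiff convention).
gsvaOracle <- function(expr, set, tau = 1) {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    h <- sd(expr[i, ]) / 4
    if (!is.finite(h) || h == 0) { z[i, ] <- 0.5; next }
    for (j in seq_len(n))
      z[i, j] <- mean(pnorm((expr[i, j] - expr[i, ]) / h))
  }
  scores <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rk <- integer(p); rk[ord] <- seq_len(p)
    s <- abs(p / 2 - rk)
    inSet <- rownames(expr) %in% set
    walk <- 0; mx <- 0; mn <- 0
    denom <- sum(s[inSet]^tau)
    for (step in seq_len(p)) {
      g <- ord[step]
      walk <- walk + if (inSet[g]) s[g]^tau / denom else -1 / (p - sum(inSet))
      mx <- max(mx, walk); mn <- min(mn, walk)
    }
    scores[j] <- mx + mn
  }
  scores
}

## Cumulative-sum enrichment score oracle (weighted KS running sum).
esOracle <- function(ranking, set, weightP = 1) {
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  hit <- genes %in% set
  w <- abs(ranking[ord])^weightP
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (length(genes) - sum(hit)))
  dev <- cumsum(inc)
  dev[which.max(abs(dev))]
}

## Exhaustive triple-loop connectome oracle: every ordered type pair x
## every ligand-receptor row.
connectomeOracle <- function(upSets, lr) {
  types <- names(upSets)
  rows <- list()
  for (s in types) for (r in types) for (i in seq_len(nrow(lr))) {
    if (lr$ligand[i] %in% upSets[[s]] && lr$receptor[i] %in% upSets[[r]])
      rows[[length(rows) + 1L]] <- data.frame(
        sender = s, receiver = r, ligand = lr$ligand[i],
        receptor = lr$receptor[i])
  }
  if (!length(rows)) return(data.frame(sender = character(),
                                       receiver = character(),
                                       ligand = character(),
                                       receptor = character()))
  do.call(rbind, rows)
}

edgeKey <- function(df) sort(paste(df$sender, df$receiver, df$ligand,
                                   df$receptor))

## Random connectome instance: <= 5 cell types, <= 20 LR pairs.
randomInstance <- function() {
  nT <- sample(2:5, 1)
  types <- paste0("T", seq_len(nT))
  genes <- paste0("G", 1:30)
  upSets <- setNames(lapply(types, function(t)
    sample(genes, sample(0:10, 1))), types)
  nP <- sample(1:20, 1)
  lr <- unique(data.frame(ligand = sample(genes, nP, replace = TRUE),
                          receptor = sample(genes, nP, replace = TRUE)))
  list(upSets = upSets, lr = lr)
}
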