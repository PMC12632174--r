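## Shared fixtures, built in code and cached for the whole run.

## Compact two-treatment config: 4 epithelial-panel types, one planted
## CNP circuit (AT2 -> AT1), 100 cells per (treatment, type) group.
smallConfig <- function(seed = 1L, ...) {
  args <- list(
    nCellTypes = 4L, nGenes = 400L, cellsPerSampleType = 50L,
    samplesPerTreatment = 2L, treatments = c("sham", "CNP"),
    markerGenesPerType = 10L, doubletRate = 0, seed = seed,
    circuits = data.frame(treatment = "CNP", sender_type = "AT2",
                          ligand = "Cxcl1", receiver_type = "AT1",
                          receptor = "Cxcr2", log2_effect = 1.5))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}

## Config with no planted effects at all (pure noise atlas).
nullConfig <- function(seed = 1L, ...) {
  smallConfig(seed = seed,
              circuits = data.frame(treatment = character(),
                                    sender_type = character(),
                                    ligand = character(),
                                    receiver_type = character(),
                                    receptor = character(),
                                    log2_effect = numeric()),
              ...)
}

.fx <- new.env()

## Normalized small atlas with planted circuit, cached across test files.
fixtureAtlas <- function() {
  if (is.null(.fx$atlas)) {
    sim <- simulateAtlas(smallConfig(seed = 42L))
    sce <- logNormalize(filterGenes(sim$sce))
    .fx$atlas <- list(sim = sim, sce = sce)
  }
  .fx$atlas
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Benjamini-Hochberg step-up computed literally from the definition.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

## Exact two-sided Wilcoxon p by enumerating every assignment of ranks.
wilcoxEnumOracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  p <- if (uObs > mu) 2 * mean(us >= uObs) else 2 * mean(us <= uObs)
  min(p, 1)
}
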