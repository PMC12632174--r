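test_that("identical configs give bitwise-identical atlases", {
  a <- simulateAtlas(smallConfig(seed = 7L))
  b <- simulateAtlas(smallConfig(seed = 7L))
  expect_identical(
    as.matrix(SummarizedExperiment::assay(a$sce, "counts")),
    as.matrix(SummarizedExperiment::assay(b$sce, "counts")))
  expect_identical(plantedDEGenes(a$truth), plantedDEGenes(b$truth))
})

test_that("a config without planted effects yields empty truth", {
  sim <- simulateAtlas(nullConfig(seed = 3L))
  expect_identical(nrow(plantedCircuits(sim$truth)), 0L)
  expect_identical(nrow(plantedDEGenes(sim$truth)), 0L)
})

test_that("configs referencing unknown types or treatments are rejected", {
  bad <- smallConfig(seed = 1L,
    circuits = data.frame(treatment = "CNP", sender_type = "Klingon",
                          ligand = "Cxcl1", receiver_type = "AT1",
                          receptor = "Cxcr2", log2_effect = 1.5))
  expect_error(simulateAtlas(bad), "unknown cell types")
  bad2 <- smallConfig(seed = 1L,
    deGenes = data.frame(treatment = "vapor", cell_type = "AT1",
                         gene = "Il33", log2_effect = 1))
  expect_error(simulateAtlas(bad2), "unknown treatments")
})

test_that("mean total counts per cell matches the NB mean-sum expectation", {
  ## neutral config: no markers boost (fold 1), no circuits, one mito gene
  nGenes <- 200L
  cfg <- nullConfig(seed = 1L, nCellTypes = 1L, nGenes = nGenes,
                    cellsPerSampleType = 100L, samplesPerTreatment = 1L,
                    treatments = "sham", baseMean = 0.5, markerFold = 1,
                    markerGenesPerType = 1L, mitoGeneFraction = 1 / nGenes)
  ## expectation computed independently: sum of NB means x E[lognormal sf];
  ## non-mito genes at baseMean, one mito gene boosted to a 4% fraction
  expectedTotal <- 0.5 * (nGenes - 1) * (1 + 0.04 / 0.96) * exp(0.3^2 / 2)
  obs <- vapply(1:10, function(s) {
    cfg@seed <- s
    sce <- simulateAtlas(cfg)$sce
    mean(Matrix::colSums(SummarizedExperiment::assay(sce, "counts")))
  }, numeric(1L))
  expect_lt(abs(mean(obs) - expectedTotal) / expectedTotal, 0.1)
})

test_that("doublet injection at rate zero is the identity", {
  sim <- simulateAtlas(smallConfig(seed = 5L))
  out <- injectDoublets(sim$sce, 0, seed = 1L)
  expect_identical(ncol(out), ncol(sim$sce))
  expect_identical(
    as.matrix(SummarizedExperiment::assay(out, "counts")),
    as.matrix(SummarizedExperiment::assay(sim$sce, "counts")))
})

test_that("injected doublets are exact sums of their parents", {
  sim <- simulateAtlas(smallConfig(seed = 5L))
  out <- injectDoublets(sim$sce, 0.1, seed = 2L)
  nd <- as.integer(round(0.1 * ncol(sim$sce)))
  expect_identical(sum(out$is_doublet), nd)
  counts <- SummarizedExperiment::assay(out, "counts")
  dbl <- which(out$is_doublet)
  for (i in dbl[1:5]) {
    parents <- strsplit(out$doublet_parents[i], "+", fixed = TRUE)[[1L]]
    expect_equal(as.numeric(counts[, i]),
                 as.numeric(counts[, parents[1L]] + counts[, parents[2L]]))
    ## column sums conserve: doublet depth = sum of parent depths
    expect_equal(sum(counts[, i]),
                 sum(counts[, parents[1L]]) + sum(counts[, parents[2L]]))
  }
  ## a cross-type doublet carries both parents' marker counts
  cross <- dbl[grepl("\\+", out$true_type[dbl]) &
                 !vapply(strsplit(out$true_type[dbl], "+", fixed = TRUE),
                         function(x) x[1L] == x[2L], logical(1L))]
  i <- cross[1L]
  parents <- strsplit(out$doublet_parents[i], "+", fixed = TRUE)[[1L]]
  expect_true(all(counts[, i] >= counts[, parents[1L]]))
  expect_true(all(counts[, i] >= counts[, parents[2L]]))
  expect_error(injectDoublets(sim$sce, 0.6), "rate")
})

test_that("LR resources contain planted pairs and separate true targets", {
  sim <- simulateAtlas(simConfig(
    seed = 2L, nCellTypes = 7L, nGenes = 800L, cellsPerSampleType = 10L,
    treatments = c("sham", "CNP", "DWCNT"), doubletRate = 0))
  genes <- rownames(sim$sce)
  ## no decoys: exactly the planted pairs
  res0 <- makeLRResources(sim$truth, genes, nDecoyPairs = 0L,
                          nDecoyLigands = 0L, seed = 1L)
  expect_identical(nrow(res0$lrPairs), nrow(plantedCircuits(sim$truth)))
  for (s in 1:5) {
    res <- makeLRResources(sim$truth, genes, nDecoyPairs = 30L,
                           nDecoyLigands = 30L, seed = s)
    rp <- res$regPotential
    expect_true(all(rp >= 0 & rp <= 1))
    tg <- plantedTargets(sim$truth)
    for (lg in unique(tg$ligand)) {
      own <- intersect(tg$gene[tg$ligand == lg], colnames(rp))
      other <- setdiff(colnames(rp), tg$gene)
      rnd <- sample(other, 100L)
      expect_gt(mean(rp[lg, own]), mean(rp[lg, rnd]))
    }
  }
  expect_error(makeLRResources(sim$truth, genes[1:50], nDecoyPairs = 100L),
               "not enough")
})

test_that("without planted effects, treatment-vs-sham mean differences are centred", {
  for (s in 1:5) {
    sce <- simulateAtlas(nullConfig(seed = s, cellsPerSampleType = 25L))$sce
    counts <- SummarizedExperiment::assay(sce, "counts")
    ## depth-normalize so that shared per-cell size factors cancel and the
    ## per-gene differences are effectively independent across genes
    norm <- counts %*% Matrix::Diagonal(x = 1e4 / Matrix::colSums(counts))
    d <- Matrix::rowMeans(norm[, sce$treatment == "CNP"]) -
      Matrix::rowMeans(norm[, sce$treatment == "sham"])
    d <- d[d != 0]
    pv <- binom.test(sum(d > 0), length(d))$p.value
    expect_gt(pv, 0.01)
  }
})

test_that("planted effects are realized at the configured magnitude", {
  ## log2_effect 1.5 at 200 cells/group: empirical log2 ratio of raw
  ## group means within +/- 0.3 for >= 90% of planted genes
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    cfg <- smallConfig(seed = s, cellsPerSampleType = 100L, baseMean = 1)
    sim <- simulateAtlas(cfg)
    counts <- SummarizedExperiment::assay(sim$sce, "counts")
    de <- plantedDEGenes(sim$truth)
    for (i in seq_len(nrow(de))) {
      trIdx <- sim$sce$treatment == de$treatment[i] &
        sim$sce$true_type == de$cell_type[i]
      shIdx <- sim$sce$treatment == "sham" &
        sim$sce$true_type == de$cell_type[i]
      ratio <- log2(mean(counts[de$gene[i], trIdx]) /
                      mean(counts[de$gene[i], shIdx]))
      hits <- hits + (abs(ratio - de$log2_effect[i]) <= 0.3)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})
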