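## SCE with given logcounts (counts set to expm1-backtransform rounding).
sceFromLogcounts <- function(lg, sample_id) {
  lg <- Matrix::Matrix(lg, sparse = TRUE)
  sce <- SingleCellExperiment::SingleCellExperiment(
    list(counts = lg, logcounts = lg))
  sce$sample_id <- sample_id
  sce
}

test_that("consensus HVGs require flagging in at least two samples", {
  set.seed(1)
  nG <- 60L; nPer <- 40L
  base <- matrix(rep(rlnorm(nG, 0, 0.1), 3L * nPer), nG, 3L * nPer)
  rownames(base) <- paste0("g", seq_len(nG))
  colnames(base) <- paste0("c", seq_len(ncol(base)))
  samples <- rep(c("s1", "s2", "s3"), each = nPer)
  ## gBoth: highly variable in s1 and s2; gOne: only in s1; gFlat: constant
  base["g1", samples != "s3"] <- rep(c(0, 4), nPer)
  base["g2", samples == "s1"] <- rep(c(0, 4), nPer / 2)
  base["g3", ] <- 1
  hv <- consensusHVGs(sceFromLogcounts(base, samples), nTop = 5L)
  expect_true("g1" %in% hv$consensus)
  expect_false("g2" %in% hv$consensus)
  expect_false("g3" %in% hv$consensus)
  expect_true(all(hv$nFlagged[hv$consensus] >= 2L))
  expect_true(all(hv$consensus %in% unique(unlist(hv$perSample))))
  expect_error(consensusHVGs(sceFromLogcounts(base, rep("s1", ncol(base)))),
               "2 samples")
})

test_that("two samples with identical matrices give the per-sample HVG set", {
  set.seed(2)
  m <- matrix(rlnorm(50 * 30), 50, 30,
              dimnames = list(paste0("g", 1:50), NULL))
  m2 <- cbind(m, m)
  colnames(m2) <- paste0("c", seq_len(60))
  hv <- consensusHVGs(sceFromLogcounts(m2, rep(c("a", "b"), each = 30)),
                      nTop = 10L)
  expect_setequal(hv$consensus, hv$perSample[["a"]])
  expect_setequal(hv$perSample[["a"]], hv$perSample[["b"]])
})

test_that("PCA embedding has the expected symmetry and ordering properties", {
  atl <- fixtureAtlas()
  hv <- consensusHVGs(atl$sce, nTop = 200L)
  eg <- embedGraph(atl$sce, hv$consensus, nPCs = 20L, k = 10L)
  expect_identical(nrow(eg$pcs), ncol(atl$sce))
  v <- apply(eg$pcs, 2L, var)
  expect_true(all(diff(v) <= 1e-8))            # PC1 var >= PC2 var >= ...
  ## duplicated cells land on identical coordinates
  sce2 <- atl$sce[, c(1:50, 1:50)]
  colnames(sce2) <- paste0("c", 1:100)
  eg2 <- embedGraph(sce2, hv$consensus, nPCs = 10L, k = 5L)
  expect_equal(eg2$pcs[1:50, ], eg2$pcs[51:100, ], ignore_attr = TRUE,
               tolerance = 1e-8)
  ## true labels explain the graph far better than permuted labels
  memb <- as.integer(factor(atl$sce$true_type))
  trueMod <- igraph::modularity(eg$graph, memb)
  set.seed(1)
  permMod <- vapply(1:100, function(i)
    igraph::modularity(eg$graph, sample(memb)), numeric(1L))
  expect_true(all(trueMod > permMod))
  expect_error(embedGraph(atl$sce, hv$consensus, k = ncol(atl$sce) + 1L),
               "fewer cells")
})

test_that("Leiden clustering separates disconnected cliques and is deterministic", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(12))
  igraph::V(g)$name <- paste0("v", seq_len(22))
  cl <- clusterLeiden(g, resolution = 1, seed = 1L)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[1:10])), 1L)
  cl2 <- clusterLeiden(g, resolution = 1, seed = 1L)
  expect_identical(cl, cl2)
  expect_error(clusterLeiden(igraph::make_empty_graph(0)), "empty")
})

test_that("Leiden recovers the planted cell types", {
  for (s in 1:2) {
    sim <- simulateAtlas(smallConfig(seed = s, markerGenesPerType = 20L))
    sce <- logNormalize(filterGenes(sim$sce))
    hv <- consensusHVGs(sce)
    eg <- embedGraph(sce, hv$consensus)
    cl <- clusterLeiden(eg$graph, seed = s)
    expect_gte(ari(cl, sce$true_type), 0.9)
  }
})

test_that("rank-sum p-values are exact for small tie-free samples", {
  set.seed(3)
  for (i in 1:10) {
    x <- sample(100, 3); y <- setdiff(sample(100, 9), x)[1:3]
    got <- wilcoxonTest(x, y)
    expect_equal(got$p, wilcoxEnumOracle(x, y), tolerance = 1e-12)
    ref <- stats::wilcox.test(x, y)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("a gene with identical values in cluster and rest scores p = 1", {
  set.seed(4)
  ps <- vapply(1:20, function(i) {
    v <- rnorm(50)
    wilcoxonTest(v, v)$p
  }, numeric(1L))
  expect_gte(mean(ps), 0.9)
})

test_that("marker detection applies both thresholds and ranks by statistic", {
  atl <- fixtureAtlas()
  mk <- rankMarkers(atl$sce, atl$sce$true_type, topN = Inf)
  expect_true(all(mk$q >= mk$p - 1e-12))
  expect_true(all(mk$q <= 1))
  ## marker flag requires BOTH conditions
  expect_identical(mk$is_marker, mk$q < 0.05 & mk$log2FC > 0.5)
  expect_false(any(mk$is_marker & mk$log2FC <= 0.5))
  ## BH within each cluster equals the step-up definition
  one <- mk[mk$cluster == "AT2", ]
  expect_equal(one$q, bhOracle(one$p), tolerance = 1e-12)
  ## ranks follow the statistic within a cluster
  expect_true(all(diff(one$statistic[order(one$rank)]) <= 1e-12))
  ## every planted marker is recovered in its own type's top list
  mk500 <- rankMarkers(atl$sce, atl$sce$true_type)
  for (tp in unique(atl$sce$true_type)) {
    planted <- paste0(tp, ".mk", 1:10)
    top <- mk500$gene[mk500$cluster == tp & mk500$is_marker]
    expect_true(all(planted %in% top))
  }
  expect_warning(rankMarkers(atl$sce, c("solo", rep("rest", ncol(atl$sce) - 1L))),
                 "fewer than 2")
})

test_that("lineage assignment follows the defining genes with a fixed tie-break", {
  genes <- c("Epcam", "Cldn5", "Col1a2", "Ptprc", paste0("g", 1:6))
  nCell <- 30L
  m <- matrix(0.1, length(genes), 3L * nCell,
              dimnames = list(genes, paste0("c", seq_len(3L * nCell))))
  cl <- rep(c("1", "2", "3"), each = nCell)
  m["Epcam", cl == "1"] <- 3            # clearly epithelial
  m["Ptprc", cl == "2"] <- 3            # clearly immune
  m["Epcam", cl == "3"] <- 2            # exact tie with Cldn5
  m["Cldn5", cl == "3"] <- 2
  sce <- sceFromLogcounts(m, rep(c("s1", "s2"), length.out = 3L * nCell))
  sce$treatment <- "sham"
  ann <- annotateTypes(sce, cl, markerReference())
  expect_identical(unique(ann$lineage[cl == "1"]), "epithelial")
  expect_identical(unique(ann$lineage[cl == "2"]), "immune")
  ## tie broken by declared lineage order: epithelial before endothelial
  expect_identical(unique(ann$lineage[cl == "3"]), "epithelial")
  ## absent defining gene is a hard error naming the lineage
  expect_error(annotateTypes(sce[rownames(sce) != "Ptprc", ], cl,
                             markerReference()),
               "Ptprc")
})

test_that("two-tier annotation recovers planted fine types within lineages", {
  sim <- simulateAtlas(simConfig(seed = 9L, nGenes = 600L,
                                 cellsPerSampleType = 25L,
                                 treatments = c("sham", "CNP"),
                                 doubletRate = 0))
  sce <- logNormalize(filterGenes(sim$sce))
  hv <- consensusHVGs(sce)
  eg <- embedGraph(sce, hv$consensus)
  cl <- clusterLeiden(eg$graph, seed = 1L)
  ann <- annotateTypes(sce, cl, sim$reference, seed = 1L)
  ## fine labels agree with the simulated truth for nearly all cells
  expect_gte(mean(ann$cell_type == ann$true_type), 0.9)
  ## tier-2 labels never cross lineage boundaries
  lin <- sim$reference@fineLineage[ann$cell_type]
  expect_true(all(lin == ann$lineage))
  ## niches follow the reference map
  expect_identical(unname(sim$reference@nicheMap[ann$cell_type]),
                   ann$niche)
})
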