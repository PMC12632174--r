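test_that("up-set extraction uses strict thresholds", {
  toy <- data.frame(
    cell_type = "AT2", treatment = "CNP", gene = paste0("g", 1:6),
    log2FC = c(2.0, 0.5, 0.51, 1.0, -1.0, 0.8),
    q = c(0.01, 0.01, 0.01, 0.20, 0.01, 0.049))
  ups <- upregulatedSets(toy)
  expect_setequal(ups$CNP$AT2, c("g1", "g3", "g6"))
  ## log2FC exactly 0.5 is excluded; q must be under the cutoff
  expect_false("g2" %in% ups$CNP$AT2)
  expect_false("g4" %in% ups$CNP$AT2)
  allNs <- toy; allNs$q <- 0.5
  expect_identical(unname(lengths(upregulatedSets(allNs)$CNP)), 0L)
})

test_that("the induced connectome matches the worked example", {
  upSets <- list(A = c("L1", "L2"), B = "R1", C = "R2")
  lr <- data.frame(ligand = c("L1", "L2", "L3"),
                   receptor = c("R1", "R2", "R1"))
  conn <- inducedConnectome(upSets, lr, "CNP")
  et <- edgeTable(conn)
  expect_identical(nrow(et), 2L)
  expect_setequal(paste(et$sender, et$receiver, et$weight),
                  c("A B 1", "A C 1"))
  expect_identical(edgeKey(conn@edges), edgeKey(connectomeOracle(upSets, lr)))
  ## empty up-sets give an empty graph
  emptyConn <- inducedConnectome(list(A = character(), B = character()),
                                 lr, "CNP")
  expect_identical(nEdges(emptyConn), 0L)
  ## duplicate LR rows are collapsed with a warning
  expect_warning(inducedConnectome(upSets, rbind(lr, lr[1, ]), "CNP"),
                 "duplicate")
})

test_that("the connectome equals exhaustive enumeration on random instances", {
  set.seed(13)
  for (i in 1:30) {
    inst <- randomInstance()
    conn <- inducedConnectome(inst$upSets, inst$lr, "t")
    expect_identical(edgeKey(conn@edges),
                     edgeKey(connectomeOracle(inst$upSets, inst$lr)))
    et <- edgeTable(conn)
    if (nrow(et)) {
      ## weight always equals the qualifying-pair count
      cnt <- table(paste(conn@edges$sender, conn@edges$receiver))
      expect_identical(et$weight[order(paste(et$sender, et$receiver))],
                       as.integer(cnt[sort(names(cnt))]))
    }
  }
})

test_that("growing an up-set never removes edges or lowers weights", {
  set.seed(14)
  for (i in 1:20) {
    inst <- randomInstance()
    conn <- inducedConnectome(inst$upSets, inst$lr, "t")
    bigger <- inst$upSets
    t <- sample(names(bigger), 1)
    bigger[[t]] <- union(bigger[[t]], sample(paste0("G", 1:30), 3))
    conn2 <- inducedConnectome(bigger, inst$lr, "t")
    expect_true(all(edgeKey(conn@edges) %in% edgeKey(conn2@edges)))
    et <- edgeTable(conn); et2 <- edgeTable(conn2)
    shared <- intersect(paste(et$sender, et$receiver),
                        paste(et2$sender, et2$receiver))
    w1 <- et$weight[match(shared, paste(et$sender, et$receiver))]
    w2 <- et2$weight[match(shared, paste(et2$sender, et2$receiver))]
    expect_true(all(w2 >= w1))
  }
})

test_that("ligand activity matches the closed-form Pearson correlation", {
  prior <- matrix(c(0.9, 0.8, 0.1, 0.1), 1, 4,
                  dimnames = list("L1", paste0("t", 1:4)))
  fr <- matrix(0.5, 1, 1, dimnames = list("A", "L1"))
  out <- ligandActivity(c("t1", "t2"), prior, fr)
  w <- c(0.9, 0.8, 0.1, 0.1); m <- c(1, 1, 0, 0)
  pcc <- sum((w - mean(w)) * (m - mean(m))) /
    sqrt(sum((w - mean(w))^2) * sum((m - mean(m))^2))
  expect_equal(out$pcc, pcc, tolerance = 1e-12)
  expect_true(out$passes_filters)
})

test_that("ligand filters follow the published cutoffs strictly", {
  set.seed(15)
  prior <- matrix(runif(3 * 50), 3, 50,
                  dimnames = list(c("La", "Lb", "Lc"), paste0("t", 1:50)))
  program <- paste0("t", 1:10)
  prior["La", ] <- c(rep(0.9, 10), rep(0.05, 40))   # strong predictor
  prior["Lc", ] <- 0.3                               # constant row
  frac <- matrix(c(0.09, 0.5, 0.5), 1, 3,
                 dimnames = list("S", c("La", "Lb", "Lc")))
  out <- ligandActivity(program, prior, frac)
  ## high PCC but 9% sender expression fails
  expect_false(out$passes_filters[out$ligand == "La"])
  ## constant regulatory-potential row is undefined, excluded
  expect_true(is.na(out$pcc[out$ligand == "Lc"]))
  expect_false(out$passes_filters[out$ligand == "Lc"])
  ## sender fraction exactly 10% passes that filter; PCC exactly at the
  ## cutoff does not (strict >)
  frac2 <- frac; frac2[1, "La"] <- 0.10
  out2 <- ligandActivity(program, prior, frac2)
  expect_true(out2$passes_filters[out2$ligand == "La"])
  ## degenerate programs leave every correlation undefined
  empty <- ligandActivity(character(), prior, frac)
  expect_false(any(empty$passes_filters))
  full <- ligandActivity(paste0("t", 1:50), prior, frac)
  expect_false(any(full$passes_filters))
})

test_that("circuit assembly is an inner join carrying weight and pcc", {
  conn <- inducedConnectome(list(A = "L1", B = c("R1", "gT")),
                            data.frame(ligand = "L1", receptor = "R1"), "CNP")
  prior <- matrix(c(0.9, 0.9, 0.1, 0.1), 1, 4,
                  dimnames = list("L1", c("gT", "t2", "t3", "t4")))
  lt <- data.frame(ligand = "L1", pcc = 0.4, max_sender_fraction = 0.5,
                   top_sender = "A", passes_filters = TRUE, receiver = "B")
  rep1 <- assembleCircuits(conn, lt, list(A = "L1", B = c("R1", "gT")), prior)
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$weight, 1L)
  expect_equal(rep1$pcc, 0.4)
  expect_identical(rep1$response_genes, "gT")
  ## no passing ligands -> empty report
  lt$passes_filters <- FALSE
  expect_identical(nrow(assembleCircuits(conn, lt,
                                         list(A = "L1", B = "R1"), prior)),
                   0L)
})

test_that("planted circuits are recovered end to end", {
  for (s in 1:2) {
    cfg <- simConfig(seed = s, nCellTypes = 7L, nGenes = 800L,
                     cellsPerSampleType = 50L,
                     treatments = c("sham", "CNP", "DWCNT"),
                     doubletRate = 0)
    sim <- simulateAtlas(cfg)
    sce <- logNormalize(filterGenes(sim$sce))
    sce$cell_type <- sce$true_type
    dge <- dgePerCellType(sce)
    res <- makeLRResources(sim$truth, rownames(sce), seed = s)
    pl <- plantedCircuits(sim$truth)
    for (trt in unique(pl$treatment)) {
      ic <- inferCircuits(sce, dge, res$lrPairs, res$regPotential, trt)
      top <- utils::head(ic$circuits, 5L)
      want <- pl[pl$treatment == trt, ]
      expect_true(paste(want$sender_type, want$ligand, want$receiver_type) %in%
                    paste(top$sender, top$ligand, top$receiver))
    }
  }
})
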