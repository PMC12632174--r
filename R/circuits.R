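## Induced connectome construction, NicheNet-style ligand activity, and
## circuit report assembly.

#' Per (treatment, cell type) upregulated gene sets
#'
#' The connectome substrate: genes with `q < fdr` and `log2FC` strictly
#' greater than `lfc` per (treatment, cell type) contrast of a DGE table.
#'
#' @param dge DGE table from [dgePerCellType()].
#' @param lfc log2FC cutoff (strict, default 0.5).
#' @param fdr FDR cutoff (strict, default 0.05).
#' @return Nested list: `upSets[[treatment]][[cell_type]]` is a character
#'   vector (possibly empty).
#' @export
upregulatedSets <- function(dge, lfc = 0.5, fdr = 0.05) {
  treatments <- unique(dge$treatment)
  types <- unique(dge$cell_type)
  out <- lapply(setNames(treatments, treatments), function(tr) {
    lapply(setNames(types, types), function(tp) {
      hit <- dge$treatment == tr & dge$cell_type == tp &
        dge$q < fdr & dge$log2FC > lfc
      dge$gene[hit]
    })
  })
  out
}

#' Induced connectome for one treatment
#'
#' Builds the treatment's cell-cell communication graph from
#' differentially upregulated genes: for every ordered (sender, receiver)
#' pair of cell types and every (ligand, receptor) row of the resource, an
#' edge sender -> receiver gains that pair iff the ligand is in the
#' sender's up-set and the receptor in the receiver's up-set. Self-edges
#' (autocrine signalling) are allowed; edge weight is the number of
#' qualifying pairs.
#'
#' @param upSets Named list cell_type -> upregulated genes (one
#'   treatment's slice of [upregulatedSets()]).
#' @param lrPairs `data.frame(ligand, receptor)`; duplicate rows are
#'   collapsed with a warning.
#' @param treatment Treatment label stored on the result.
#' @return A [Connectome-class] object.
#' @export
inducedConnectome <- function(upSets, lrPairs, treatment = "treatment") {
  stopifnot(is.list(upSets), !is.null(names(upSets)))
  lr <- unique(lrPairs[, c("ligand", "receptor")])
  if (nrow(lr) < nrow(lrPairs))
    warning("collapsed ", nrow(lrPairs) - nrow(lr),
            " duplicate ligand-receptor rows")
  types <- names(upSets)
  edges <- list()
  for (i in seq_len(nrow(lr))) {
    senders <- types[vapply(upSets, function(s) lr$ligand[i] %in% s,
                            logical(1L))]
    receivers <- types[vapply(upSets, function(s) lr$receptor[i] %in% s,
                              logical(1L))]
    if (length(senders) && length(receivers)) {
      g <- expand.grid(sender = senders, receiver = receivers,
                       stringsAsFactors = FALSE)
      g$ligand <- lr$ligand[i]
      g$receptor <- lr$receptor[i]
      edges[[length(edges) + 1L]] <- g
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(sender = character(), receiver = character(),
               ligand = character(), receptor = character())
  rownames(edges) <- NULL
  methods::new("Connectome", treatment = treatment, edges = edges,
               cellTypes = types)
}

#' Fraction of cells expressing each gene, per cell type
#'
#' @param sce A `SingleCellExperiment` with a raw `counts` assay.
#' @param genes Genes to evaluate (default all).
#' @param typeCol colData column holding the cell-type label.
#' @param treatment Optional treatment label to restrict cells to.
#' @return Matrix cell types x genes of expressing-cell fractions.
#' @export
expressionFractions <- function(sce, genes = NULL, typeCol = "cell_type",
                                treatment = NULL) {
  counts <- .assayCounts(sce)
  cd <- SummarizedExperiment::colData(sce)
  keep <- rep(TRUE, ncol(counts))
  if (!is.null(treatment)) keep <- as.character(cd$treatment) == treatment
  if (is.null(genes)) genes <- rownames(counts)
  genes <- intersect(genes, rownames(counts))
  types <- as.character(cd[[typeCol]])[keep]
  counts <- counts[genes, keep, drop = FALSE]
  res <- vapply(sort(unique(types)), function(tp)
    as.numeric(Matrix::rowMeans(counts[, types == tp, drop = FALSE] > 0)),
    numeric(length(genes)))
  t(matrix(res, length(genes), dimnames = list(genes, sort(unique(types)))))
}

#' NicheNet-style ligand activity for one receiver program
#'
#' For each ligand of the regulatory-potential prior, the predictive
#' ability is the Pearson correlation between the ligand's
#' regulatory-potential vector over the prior's target universe and the
#' 0/1 membership vector of the receiver cell type's perturbed gene
#' program. A ligand passes the filters iff some sender cell type
#' expresses it in at least `minSenderFrac` of its cells and the
#' correlation is strictly greater than `minPcc`. Constant
#' regulatory-potential rows, and degenerate programs (empty or covering
#' the whole target universe), leave the correlation undefined and the
#' ligand excluded.
#'
#' @param program Character vector: the receiver's perturbed gene program
#'   (typically its upregulated set).
#' @param prior Numeric matrix ligands x targets with weights in `[0, 1]`.
#' @param senderFractions Matrix sender types x genes from
#'   [expressionFractions()] (evaluated on the treatment's cells).
#' @param testedGenes Optional: restrict the target universe to genes
#'   actually tested in the DGE (genes untested are dropped from both
#'   vectors).
#' @param minSenderFrac Sender expression filter (default 0.10).
#' @param minPcc Correlation filter (default 0.05, strict).
#' @return `data.frame(ligand, pcc, max_sender_fraction, top_sender,
#'   passes_filters)`, sorted by decreasing correlation.
#' @export
ligandActivity <- function(program, prior, senderFractions,
                           testedGenes = NULL, minSenderFrac = 0.10,
                           minPcc = 0.05) {
  targets <- colnames(prior)
  if (!is.null(testedGenes)) targets <- intersect(targets, testedGenes)
  if (length(targets) < 3L)
    stop("prior target universe does not overlap the tested genes")
  membership <- as.numeric(targets %in% program)
  constantProgram <- sd(membership) == 0
  ligands <- rownames(prior)
  pcc <- vapply(ligands, function(l) {
    w <- prior[l, targets]
    if (constantProgram || sd(w) == 0) return(NA_real_)
    cor(w, membership)
  }, numeric(1L))
  known <- intersect(ligands, colnames(senderFractions))
  maxFrac <- setNames(rep(NA_real_, length(ligands)), ligands)
  topSender <- setNames(rep(NA_character_, length(ligands)), ligands)
  if (length(known)) {
    sub <- senderFractions[, known, drop = FALSE]
    maxFrac[known] <- apply(sub, 2L, max)
    topSender[known] <- rownames(sub)[apply(sub, 2L, which.max)]
  }
  passes <- !is.na(pcc) & pcc > minPcc &
    !is.na(maxFrac) & maxFrac >= minSenderFrac
  out <- data.frame(ligand = ligands, pcc = pcc,
                    max_sender_fraction = maxFrac,
                    top_sender = topSender, passes_filters = passes)
  rownames(out) <- NULL
  out[order(-ifelse(is.na(out$pcc), -Inf, out$pcc)), , drop = FALSE]
}

#' Assemble the per-treatment circuit report
#'
#' Inner join of the connectome's edges with the passing ligand-activity
#' rows on (ligand, receiver): every reported circuit is supported by both
#' a differential ligand-receptor edge and a passing ligand activity.
#' Rows are ranked by (pcc, weight) descending; the receiver response
#' genes are the receiver's up-set intersected with the ligand's
#' above-median regulatory-potential targets.
#'
#' @param connectome A [Connectome-class].
#' @param ligandTable Ligand-activity rows carrying a `receiver` column
#'   (rbind of per-receiver [ligandActivity()] outputs).
#' @param upSets Named list cell_type -> upregulated genes for the same
#'   treatment.
#' @param prior Regulatory-potential matrix (ligands x targets).
#' @return `data.frame(treatment, sender, ligand, receiver, receptor,
#'   weight, pcc, response_genes)`, one row per supported
#'   (sender, ligand, receiver, receptor) tuple.
#' @export
assembleCircuits <- function(connectome, ligandTable, upSets, prior) {
  stopifnot(methods::is(connectome, "Connectome"))
  ed <- connectome@edges
  lt <- ligandTable[ligandTable$passes_filters, , drop = FALSE]
  empty <- data.frame(treatment = character(), sender = character(),
                      ligand = character(), receiver = character(),
                      receptor = character(), weight = integer(),
                      pcc = numeric(), response_genes = character())
  if (!nrow(ed) || !nrow(lt)) return(empty)
  et <- edgeTable(connectome)
  wkey <- setNames(et$weight, paste(et$sender, et$receiver))
  j <- merge(ed, lt[, c("ligand", "receiver", "pcc")],
             by.x = c("ligand", "receiver"),
             by.y = c("ligand", "receiver"))
  if (!nrow(j)) return(empty)
  j$weight <- unname(wkey[paste(j$sender, j$receiver)])
  j$response_genes <- vapply(seq_len(nrow(j)), function(i) {
    lg <- j$ligand[i]
    if (!lg %in% rownames(prior)) return("")
    w <- prior[lg, ]
    strong <- colnames(prior)[w > stats::median(w)]
    paste(intersect(upSets[[j$receiver[i]]], strong), collapse = ";")
  }, character(1L))
  j <- j[order(-j$pcc, -j$weight, j$sender, j$receiver), , drop = FALSE]
  out <- data.frame(treatment = connectome@treatment, sender = j$sender,
                    ligand = j$ligand, receiver = j$receiver,
                    receptor = j$receptor, weight = j$weight, pcc = j$pcc,
                    response_genes = j$response_genes)
  rownames(out) <- NULL
  out
}

#' One-call circuit inference for a treatment
#'
#' Convenience wrapper chaining [upregulatedSets()],
#' [inducedConnectome()], per-receiver [ligandActivity()] (sender
#' expression fractions evaluated on the treatment's cells) and
#' [assembleCircuits()].
#'
#' @param sce Annotated `SingleCellExperiment` with `counts` and
#'   `logcounts` assays.
#' @param dge DGE table from [dgePerCellType()].
#' @param lrPairs `data.frame(ligand, receptor)`.
#' @param prior Regulatory-potential matrix (ligands x targets).
#' @param treatment Treatment to analyse.
#' @param typeCol colData column holding the cell-type label.
#' @param minSenderFrac,minPcc Ligand filters.
#' @param lfc,fdr Up-set thresholds.
#' @return A list with `connectome`, `ligands` (all receivers' activity
#'   rows) and `circuits` (the assembled report).
#' @export
inferCircuits <- function(sce, dge, lrPairs, prior, treatment,
                          typeCol = "cell_type", minSenderFrac = 0.10,
                          minPcc = 0.05, lfc = 0.5, fdr = 0.05) {
  ups <- upregulatedSets(dge, lfc = lfc, fdr = fdr)[[treatment]]
  if (is.null(ups)) stop("treatment '", treatment, "' not present in DGE")
  conn <- inducedConnectome(ups, lrPairs, treatment)
  fr <- expressionFractions(sce, genes = rownames(prior),
                            typeCol = typeCol, treatment = treatment)
  tested <- unique(dge$gene[dge$treatment == treatment])
  ligands <- do.call(rbind, lapply(names(ups), function(recv) {
    if (!length(ups[[recv]])) return(NULL)
    la <- ligandActivity(ups[[recv]], prior, fr, testedGenes = tested,
                         minSenderFrac = minSenderFrac, minPcc = minPcc)
    la$receiver <- recv
    la
  }))
  if (is.null(ligands))
    ligands <- data.frame(ligand = character(), pcc = numeric(),
                          max_sender_fraction = numeric(),
                          top_sender = character(),
                          passes_filters = logical(),
                          receiver = character())
  circuits <- assembleCircuits(conn, ligands, ups, prior)
  list(connectome = conn, ligands = ligands, circuits = circuits)
}
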