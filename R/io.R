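## Plain-text readers/writers for the pipeline's exchange formats:
## Matrix Market counts + name TSVs (10x style), cell metadata, GMT gene
## sets, ligand-receptor tables, regulatory-potential matrices,
## connectome exports. Every writer has a matching reader.

#' Write a count matrix as Matrix Market triplet plus name files
#'
#' Writes `matrix.mtx`, `genes.tsv` (one symbol per line) and
#' `barcodes.tsv` into `dir`, the 10x-style layout.
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay (or a sparse
#'   genes x cells matrix).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCountsMM <- function(sce, dir) {
  counts <- if (methods::is(sce, "SummarizedExperiment"))
    .assayCounts(sce) else sce
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a Matrix Market count directory
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`.
#' @param meta Optional path to a cell-metadata TSV (barcodes as first
#'   column) attached as colData.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @export
readCountsMM <- function(dir, meta = NULL) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  cd <- if (!is.null(meta)) {
    md <- read.delim(meta, row.names = 1L, check.names = FALSE)
    S4Vectors::DataFrame(md[colnames(counts), , drop = FALSE])
  } else NULL
  if (is.null(cd)) {
    SingleCellExperiment::SingleCellExperiment(list(counts = counts))
  } else {
    SingleCellExperiment::SingleCellExperiment(list(counts = counts),
                                               colData = cd)
  }
}

#' Write cell metadata as TSV
#' @param sce A `SingleCellExperiment`.
#' @param file Output path.
#' @export
writeCellMeta <- function(sce, file) {
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  write.table(cbind(barcode = colnames(sce), cd), file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read gene sets in GMT format
#'
#' @param file Path to a GMT file (set name, description, then genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
readGMT <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1L), 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param file Output path.
#' @export
writeGMT <- function(sets, file) {
  stopifnot(!is.null(names(sets)))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1L)), file)
  invisible(file)
}

#' Read / write a two-column ligand-receptor pair table
#' @param file TSV path with columns `ligand` and `receptor`.
#' @return `data.frame(ligand, receptor)`.
#' @export
readLRPairs <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("ligand", "receptor") %in% names(df)))
  df[, c("ligand", "receptor")]
}

#' @rdname readLRPairs
#' @param lrPairs `data.frame(ligand, receptor)`.
#' @export
writeLRPairs <- function(lrPairs, file) {
  write.table(lrPairs[, c("ligand", "receptor")], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write a regulatory-potential matrix as dense TSV
#' @param file TSV path; rows are ligands, columns target genes.
#' @return Numeric matrix.
#' @export
readRegPotential <- function(file) {
  as.matrix(read.delim(file, row.names = 1L, check.names = FALSE))
}

#' @rdname readRegPotential
#' @param prior Numeric matrix ligands x targets.
#' @export
writeRegPotential <- function(prior, file) {
  write.table(data.frame(ligand = rownames(prior), prior,
                         check.names = FALSE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export a connectome as edge-list TSV and GraphML
#'
#' @param connectome A [Connectome-class].
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return Character vector of the written paths, invisibly.
#' @export
writeConnectome <- function(connectome, prefix) {
  et <- edgeTable(connectome)
  edgeFile <- paste0(prefix, "_edges.tsv")
  write.table(et, edgeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  gmlFile <- paste0(prefix, ".graphml")
  igraph::write_graph(asIgraph(connectome), gmlFile, format = "graphml")
  invisible(c(edgeFile, gmlFile))
}

#' Write / read planted simulation truth as JSON
#' @param truth A [PlantedTruth-class].
#' @param file Output path.
#' @export
writeTruth <- function(truth, file) {
  jsonlite::write_json(list(circuits = truth@circuits,
                            de_genes = truth@deGenes,
                            targets = truth@targets),
                       file, digits = NA)
  invisible(file)
}

#' @rdname writeTruth
#' @export
readTruth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  asDf <- function(d, cols) {
    if (is.null(d) || !length(d)) {
      d <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
    }
    as.data.frame(d)
  }
  methods::new("PlantedTruth",
    circuits = asDf(x$circuits, c("treatment", "sender_type", "ligand",
                                  "receiver_type", "receptor", "log2_effect")),
    deGenes = asDf(x$de_genes, c("treatment", "cell_type", "gene",
                                 "log2_effect")),
    targets = asDf(x$targets, c("treatment", "ligand", "receiver_type",
                                "gene")))
}
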