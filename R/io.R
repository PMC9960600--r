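#' Read a 10x-convention MatrixMarket count directory
#'
#' Expects `matrix.mtx` plus `barcodes.tsv` and either `features.tsv`
#' (three-column: id, symbol, type) or `genes.tsv` (two-column: id,
#' symbol). Gene symbols are used as row names when present (made unique),
#' otherwise the ids.
#'
#' @param dir directory containing the triplet.
#' @return A `SingleCellExperiment` with a sparse `counts` assay.
#' @seealso [writeCounts10x()], [readCountsCSV()]
#' @export
readCounts10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in ", dir)
  m <- Matrix::readMM(mtx)
  featFile <- file.path(dir, "features.tsv")
  if (!file.exists(featFile)) featFile <- file.path(dir, "genes.tsv")
  if (!file.exists(featFile))
    stop("no features.tsv or genes.tsv in ", dir)
  feats <- utils::read.table(featFile, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.table(file.path(dir, "barcodes.tsv"),
                                sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[, 1L]
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
    stop("feature/barcode files do not match the matrix dimensions")
  ids <- if (ncol(feats) >= 2L) feats[, 2L] else feats[, 1L]
  rownames(m) <- make.unique(as.character(ids))
  colnames(m) <- make.unique(as.character(barcodes))
  m <- methods::as(m, "CsparseMatrix")
  .rebuildSCE(m)
}

#' Write a count matrix as a 10x-convention MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `features.tsv` (id, symbol, "Gene Expression") and
#' `barcodes.tsv`; when the container carries a `Group` column (simulated
#' truth) it is additionally written to `truth.csv`.
#'
#' @param x a count container accepted by [filterCellsAndGenes()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeCounts10x <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- .getCounts(x)
  Matrix::writeMM(methods::as(methods::as(m, "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(rownames(m), rownames(m), "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (is(x, "SummarizedExperiment")) {
    grp <- SummarizedExperiment::colData(x)$Group
    if (!is.null(grp))
      utils::write.csv(data.frame(cell_id = colnames(m), group = grp),
                       file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dense genes-by-cells count table
#'
#' CSV or TSV (decided by extension, overridable) with a header row of
#' cell identifiers and gene identifiers in the first column.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @export
readCountsCSV <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t"
           else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (any(m < 0)) stop("counts must be non-negative")
  .rebuildSCE(m)
}

#' Read / write embedded coordinates
#'
#' CSV with columns `cell_id`, `dim1`, ..., `dimd`.
#'
#' @param x an [EmbeddedDataset-class] (writer).
#' @param path file path.
#' @return `readEmbedding` returns an [EmbeddedDataset-class];
#'   `writeEmbedding` invisibly returns `path`.
#' @export
writeEmbedding <- function(x, path) {
  xy <- coords(x)
  df <- data.frame(cell_id = cellIds(x), xy)
  names(df)[-1L] <- paste0("dim", seq_len(ncol(xy)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  EmbeddedDataset(as.matrix(df[, -1L, drop = FALSE]),
                  cellIds = as.character(df[[1L]]))
}

#' Read / write cluster labels
#'
#' CSV with columns `cell_id`, `label`.
#'
#' @param assignment a [ClusterAssignment-class] or label vector.
#' @param cellIds cell identifiers matching the labels.
#' @param path file path.
#' @return `readLabels` returns a named integer vector; `writeLabels`
#'   invisibly returns `path`.
#' @export
writeLabels <- function(assignment, cellIds, path) {
  labels <- if (is(assignment, "ClusterAssignment"))
    clusterLabels(assignment) else as.integer(assignment)
  utils::write.csv(data.frame(cell_id = cellIds, label = labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as.integer(df$label), df$cell_id)
}

#' Write cluster prototypes
#'
#' CSV with columns `cluster`, `coord_1`, ..., `coord_d`.
#'
#' @param prototypes `k x d` prototype matrix.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
writePrototypes <- function(prototypes, path) {
  prototypes <- as.matrix(prototypes)
  df <- data.frame(cluster = seq_len(nrow(prototypes)), prototypes)
  names(df)[-1L] <- paste0("coord_", seq_len(ncol(prototypes)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
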