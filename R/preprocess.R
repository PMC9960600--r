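## extract the raw count matrix (genes x cells) plus ids from any of the
## accepted containers: SingleCellExperiment / SummarizedExperiment with a
## "counts" assay, or a plain (possibly sparse) matrix.
.getCounts <- function(x) {
  m <- if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    x
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("gene_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("cell_", seq_len(ncol(m)))
  m
}

## rebuild a SingleCellExperiment around a modified count matrix, carrying
## over colData rows for the surviving (or duplicated) cells.
.rebuildSCE <- function(m, template = NULL, cellIdx = NULL) {
  cd <- NULL
  if (!is.null(template) && is(template, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(template)
    if (!is.null(cellIdx)) cd <- cd[cellIdx, , drop = FALSE]
    rownames(cd) <- colnames(m)
  }
  if (is.null(cd))
    cd <- S4Vectors::DataFrame(row.names = colnames(m))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
}

#' Filter cells and genes of a raw count matrix
#'
#' Quality-control filtering in four ordered steps: (1) remove genes
#' expressed in fewer than `minCellsPerGene` cells; (2) remove cells with
#' fewer than `minGenesPerCell` expressed genes; (3) remove cells whose
#' mitochondrial count fraction (genes whose id starts with `mitoPrefix`,
#' case-insensitively) exceeds `maxMitoFraction`; (4) remove cells whose
#' total mRNA count or total expressed-gene count falls outside
#' `10^(mean(log10 x) +/- outlierSD * sd(log10 x))`, the moments taken over
#' the cells retained after step 3.
#'
#' Note that step 4 is a one-shot trim: re-applying the filter recomputes
#' the moments over the survivors, whose spread is necessarily smaller, so
#' strict idempotence holds for steps 1-3 but only approximately for the
#' outlier step.
#'
#' @param x a `SingleCellExperiment`/`SummarizedExperiment` with a
#'   `counts` assay, or a genes-x-cells count matrix.
#' @param config a [PreprocessConfig-class].
#' @return A `SingleCellExperiment` containing the surviving submatrix;
#'   `metadata(.)$filterLog` holds a per-step removal log and the outlier
#'   bounds used.
#' @export
filterCellsAndGenes <- function(x, config = preprocessConfig()) {
  m <- .getCounts(x)
  if (any(m < 0)) stop("counts must be non-negative")
  log <- data.frame(step = character(0), removedGenes = integer(0),
                    removedCells = integer(0))
  note <- function(step, g, c) rbind(log, data.frame(
    step = step, removedGenes = g, removedCells = c))
  fail <- function(step) stop("all cells removed at step '", step, "'")

  keepG <- Matrix::rowSums(m > 0) >= config@minCellsPerGene
  log <- note("gene_min_cells", sum(!keepG), 0L)
  m <- m[keepG, , drop = FALSE]

  genesPerCell <- Matrix::colSums(m > 0)
  keepC <- genesPerCell >= config@minGenesPerCell
  log <- note("cell_min_genes", 0L, sum(!keepC))
  m <- m[, keepC, drop = FALSE]
  if (ncol(m) == 0L) fail("cell_min_genes")

  mito <- grepl(paste0("^", config@mitoPrefix), rownames(m),
                ignore.case = TRUE)
  if (any(mito)) {
    frac <- Matrix::colSums(m[mito, , drop = FALSE]) / Matrix::colSums(m)
    keepC <- frac <= config@maxMitoFraction
  } else {
    keepC <- rep(TRUE, ncol(m))
  }
  log <- note("cell_mito_fraction", 0L, sum(!keepC))
  m <- m[, keepC, drop = FALSE]
  if (ncol(m) == 0L) fail("cell_mito_fraction")

  bounds <- list()
  keepC <- rep(TRUE, ncol(m))
  for (what in c("total_counts", "total_genes")) {
    v <- if (what == "total_counts") Matrix::colSums(m) else
      Matrix::colSums(m > 0)
    lv <- log10(pmax(v, .Machine$double.xmin))
    mu <- mean(lv); sd <- stats::sd(lv)
    if (is.na(sd)) sd <- 0
    lo <- 10^(mu - config@outlierSD * sd)
    hi <- 10^(mu + config@outlierSD * sd)
    bounds[[what]] <- c(lo = lo, hi = hi)
    # tolerance so sd = 0 bounds keep cells sitting exactly on them
    keepC <- keepC & v >= lo * (1 - 1e-12) & v <= hi * (1 + 1e-12)
  }
  log <- note("cell_outlier_bounds", 0L, sum(!keepC))
  m <- m[, keepC, drop = FALSE]
  if (ncol(m) == 0L) fail("cell_outlier_bounds")

  cellIdx <- match(colnames(m), colnames(.getCounts(x)))
  out <- .rebuildSCE(m, template = x, cellIdx = cellIdx)
  S4Vectors::metadata(out)$filterLog <- list(steps = log, bounds = bounds)
  out
}

## vst-style standardized variance: fit a loess trend of log10 variance on
## log10 mean over positive-variance genes, standardize each gene's counts
## by the trend-expected sd, clip at sqrt(n), and take the variance of the
## clipped values.
.standardizedVariance <- function(m) {
  n <- ncol(m)
  mu <- as.numeric(Matrix::rowMeans(m))
  v <- as.numeric(Matrix::rowMeans(m^2) - mu^2) * n / max(1L, n - 1L)
  sv <- numeric(nrow(m))
  usable <- v > 0 & mu > 0
  if (sum(usable) < 3L || n < 2L) {
    sv[usable] <- v[usable]
    return(sv)
  }
  fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = 0.3,
                      degree = 2)
  expSD <- sqrt(10^stats::fitted(fit))
  clipMax <- sqrt(n)
  dense <- as.matrix(m[usable, , drop = FALSE])
  z <- (dense - mu[usable]) / expSD
  z[z > clipMax] <- clipMax
  z[z < -clipMax] <- -clipMax
  zm <- rowMeans(z)
  sv[usable] <- (rowMeans(z^2) - zm^2) * n / (n - 1L)
  sv
}

#' Select highly variable genes
#'
#' Models the mean-variance relationship of raw counts (loess trend of
#' log10 variance against log10 mean), standardizes each gene's variance by
#' the trend expectation with clipping at `sqrt(n)`, and keeps the `nHVG`
#' genes with the largest standardized variance. Ties are broken by gene
#' id so the selection is invariant to gene ordering. When fewer than
#' `nHVG` genes are available all are kept with a warning.
#'
#' @inheritParams filterCellsAndGenes
#' @return A `SingleCellExperiment` restricted to the selected genes, in
#'   their original order; `metadata(.)$hvg` records ids and scores.
#' @export
selectHVG <- function(x, config = preprocessConfig()) {
  m <- .getCounts(x)
  g <- nrow(m)
  if (g <= config@nHVG) {
    if (g < config@nHVG)
      warning("only ", g, " genes available; keeping all")
    out <- .rebuildSCE(m, template = x,
                       cellIdx = seq_len(ncol(m)))
    S4Vectors::metadata(out)$hvg <-
      data.frame(gene = rownames(m), score = .standardizedVariance(m))
    return(out)
  }
  sv <- .standardizedVariance(m)
  ord <- order(-sv, rownames(m))
  keep <- sort(ord[seq_len(config@nHVG)])
  out <- .rebuildSCE(m[keep, , drop = FALSE], template = x,
                     cellIdx = seq_len(ncol(m)))
  S4Vectors::metadata(out)$hvg <-
    data.frame(gene = rownames(m)[keep], score = sv[keep])
  out
}

#' Log-normalize and scale a count matrix
#'
#' Per-cell library-size normalization to the median library size, `log1p`
#' transformation, then per-gene standardization so every gene has mean 0
#' and variance 1 across cells (genes with zero variance map to all
#' zeros).
#'
#' @inheritParams filterCellsAndGenes
#' @param x counts container as in [filterCellsAndGenes()].
#' @return Dense numeric matrix (genes x cells) of scaled expression.
#' @export
logNormalizeScale <- function(x) {
  m <- as.matrix(.getCounts(x))
  if (any(m < 0)) stop("counts must be non-negative")
  lib <- colSums(m)
  if (any(lib == 0)) stop("cells with zero total counts cannot be normalized")
  target <- stats::median(lib)
  norm <- log1p(sweep(m, 2L, lib, "/") * target)
  mu <- rowMeans(norm)
  sd <- sqrt(rowSums((norm - mu)^2) / max(1L, ncol(norm) - 1L))
  scaled <- (norm - mu) / ifelse(sd > 0, sd, 1)
  scaled[sd == 0, ] <- 0
  scaled
}

#' Reduce scaled expression to a low-dimensional embedding
#'
#' Exact PCA (singular value decomposition of the cells-x-genes matrix,
#' with the deterministic sign convention that each component's
#' largest-magnitude loading is positive) to `nPCs` components, followed by
#' the configured 2-D reducer: `"umap"` runs a seeded single-threaded UMAP
#' on the principal components, `"pca"` simply keeps the first `embedDims`
#' components and is exactly deterministic and permutation-equivariant.
#'
#' @param x scaled genes-x-cells matrix from [logNormalizeScale()].
#' @param config a [PreprocessConfig-class].
#' @return An [EmbeddedDataset-class]; `metadata(.)$explainedVariance`
#'   holds the per-PC explained variance fractions.
#' @export
reduceDimensions <- function(x, config = preprocessConfig()) {
  X <- t(as.matrix(x))                    # cells x genes
  n <- nrow(X)
  if (n < config@embedDims)
    stop("need at least ", config@embedDims, " cells")
  npc <- min(config@nPCs, n, ncol(X))
  sv <- svd(X, nu = npc, nv = npc)
  flip <- vapply(seq_len(npc), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u, 2L, sv$d[seq_len(npc)] * flip, "*")
  explained <- sv$d^2 / sum(sv$d^2)
  emb <- if (config@reducer == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE))
      stop("the 'uwot' package is required for reducer = \"umap\"; ",
           "use reducer = \"pca\" otherwise")
    set.seed(config@seed)
    uwot::umap(scores, n_components = config@embedDims,
               n_neighbors = min(15L, n - 1L), min_dist = 0.1,
               n_threads = 1L, n_sgd_threads = 0L)
  } else {
    scores[, seq_len(config@embedDims), drop = FALSE]
  }
  EmbeddedDataset(emb, cellIds = rownames(X),
                  metadata = list(explainedVariance =
                                    explained[seq_len(npc)]))
}

#' Run the full preprocessing workflow
#'
#' Filtering, highly-variable-gene selection, log-normalization and
#' scaling, PCA and 2-D embedding, in that order.
#'
#' @inheritParams filterCellsAndGenes
#' @return An [EmbeddedDataset-class] whose metadata collects the filter
#'   log, selected genes and per-PC explained variance.
#' @examples
#' sce <- simulateCounts(simulationConfig(nCells = 120, nGenes = 300,
#'                                        nGroups = 2, seed = 1))
#' ed <- preprocessCounts(sce, preprocessConfig(minGenesPerCell = 10,
#'                                              reducer = "pca"))
#' @export
preprocessCounts <- function(x, config = preprocessConfig()) {
  filtered <- filterCellsAndGenes(x, config)
  hvg <- selectHVG(filtered, config)
  scaled <- logNormalizeScale(hvg)
  ed <- reduceDimensions(scaled, config)
  ed@metadata <- c(ed@metadata,
                   S4Vectors::metadata(filtered)["filterLog"],
                   S4Vectors::metadata(hvg)["hvg"])
  ed
}
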