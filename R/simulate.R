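#' Simulate grouped single-cell RNA-seq counts
#'
#' Hierarchical gamma-Poisson generator of grouped count data with known
#' cell memberships, in the spirit of the Splatter simulator's core model:
#' gene base means are Gamma distributed; each group up- or down-regulates
#' a `deProb` fraction of genes by log-normal multipliers; cell library
#' sizes are log-normal; and counts are Poisson around the library-scaled,
#' per-group normalized expression profile. Dropout, batch effects and
#' overdispersion beyond the gamma mixing are intentionally omitted: the
#' generator's purpose is benchmarks with known groups of tunable
#' separation.
#'
#' @param config a [SimulationConfig-class].
#' @return A `SingleCellExperiment` with a `counts` assay (genes x cells)
#'   and the true group labels in `colData(.)$Group`;
#'   `metadata(.)$simulation` records the configuration.
#' @examples
#' sce <- simulateCounts(simulationConfig(nCells = 100, nGenes = 200,
#'                                        nGroups = 2, seed = 7))
#' table(SingleCellExperiment::colData(sce)$Group)
#' @seealso [simulateEmbedded()]
#' @export
simulateCounts <- function(config = simulationConfig()) {
  validObject(config)
  set.seed(config@seed)
  g <- config@nGenes; n <- config@nCells; k <- config@nGroups

  baseMean <- stats::rgamma(g, shape = config@geneMeanShape,
                            rate = config@geneMeanRate)
  groupMeans <- matrix(baseMean, nrow = g, ncol = k)
  for (grp in seq_len(k)) {
    de <- stats::runif(g) < config@deProb
    fac <- stats::rlnorm(sum(de), meanlog = config@deFactorLocation,
                         sdlog = config@deFactorScale)
    down <- stats::runif(sum(de)) < 0.5
    fac[down] <- 1 / fac[down]
    groupMeans[de, grp] <- groupMeans[de, grp] * fac
  }
  profile <- sweep(groupMeans, 2L, colSums(groupMeans), "/")

  groups <- sample.int(k, n, replace = TRUE, prob = config@groupProbs)
  lib <- stats::rlnorm(n, meanlog = config@libLocation,
                       sdlog = config@libScale)
  lambda <- profile[, groups, drop = FALSE] *
    rep(lib, each = g)
  counts <- matrix(stats::rpois(g * n, lambda), nrow = g, ncol = n)
  rownames(counts) <- sprintf("gene_%05d", seq_len(g))
  colnames(counts) <- sprintf("cell_%05d", seq_len(n))

  cd <- S4Vectors::DataFrame(
    Group = factor(sprintf("Group%d", groups),
                   levels = sprintf("Group%d", seq_len(k))),
    row.names = colnames(counts))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  S4Vectors::metadata(sce)$simulation <- config
  sce
}

#' Simulate an embedded Gaussian-mixture dataset
#'
#' Fast fixture generator for the evolutionary engine: isotropic Gaussian
#' blobs of equal size (up to remainder) around the given centers.
#'
#' @param nCells total number of cells.
#' @param centers `k x d` matrix of blob centers.
#' @param sigma isotropic standard deviation of each blob.
#' @param seed integer seed.
#' @return List with `data` (an [EmbeddedDataset-class]) and `truth`
#'   (integer blob labels in `1..k`).
#' @examples
#' sim <- simulateEmbedded(100, rbind(c(0, 0), c(10, 0)), sigma = 0.5,
#'                         seed = 1)
#' @export
simulateEmbedded <- function(nCells, centers, sigma = 1, seed = 1L) {
  centers <- as.matrix(centers)
  k <- nrow(centers); d <- ncol(centers)
  if (k < 1L) stop("at least one center is required")
  if (sigma <= 0) stop("'sigma' must be positive")
  set.seed(as.integer(seed))
  sizes <- rep(nCells %/% k, k)
  extra <- nCells %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  truth <- rep(seq_len(k), times = sizes)
  x <- centers[truth, , drop = FALSE] +
    matrix(stats::rnorm(nCells * d, sd = sigma), nrow = nCells)
  list(data = EmbeddedDataset(x), truth = truth)
}

#' True group labels of a simulated dataset
#'
#' Convenience accessor for the `Group` column written by
#' [simulateCounts()], restricted (by cell id) to the cells surviving
#' preprocessing when an [EmbeddedDataset-class] is given.
#'
#' @param x the `SingleCellExperiment` returned by [simulateCounts()].
#' @param embedded optional [EmbeddedDataset-class] produced from `x`; when
#'   supplied, labels are returned for its cells only, in its order.
#' @return Factor of group labels.
#' @export
trueLabels <- function(x, embedded = NULL) {
  labels <- SummarizedExperiment::colData(x)$Group
  if (is.null(labels)) stop("no 'Group' column in colData")
  names(labels) <- colnames(x)
  if (!is.null(embedded)) labels <- labels[cellIds(embedded)]
  labels
}
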