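#' Apply a metamorphic perturbation
#'
#' The six metamorphic relations used to probe clustering stability:
#'
#' * `MR1` — permute the order of cells (seeded random permutation);
#' * `MR2` — multiply the counts of one seeded-random gene by `factor`,
#'   rounding to integers;
#' * `MR3` — append a duplicate of one seeded-random cell under a fresh id;
#' * `MR4` — permute the order of genes;
#' * `MR5` — append a pseudo-gene with constant count `value` (zero
#'   variance) across all cells;
#' * `MR6` — negate all embedded coordinates (a global point reflection,
#'   i.e. a Euclidean isometry).
#'
#' Relations MR1-MR5 act on a count container; MR6 acts on an
#' [EmbeddedDataset-class], because negated raw counts are incompatible
#' with the logarithmic transform of the preprocessing stage, whereas
#' negated coordinates leave every Euclidean quantity of a fixed labeling
#' unchanged.
#'
#' @param x a `SingleCellExperiment`/count matrix (MR1-MR5) or an
#'   [EmbeddedDataset-class] (MR6).
#' @param relation one of `"MR1" ... "MR6"`.
#' @param seed seed for the random choices of MR1-MR4.
#' @param factor multiplier for MR2 (default 2).
#' @param value constant count of the MR5 pseudo-gene (default 1).
#' @return An object of the same type as `x`.
#' @examples
#' sce <- simulateCounts(simulationConfig(nCells = 50, nGenes = 100,
#'                                        seed = 1))
#' dim(applyMetamorphic(sce, "MR5"))
#' @export
applyMetamorphic <- function(x, relation, seed = 1L, factor = 2,
                             value = 1L) {
  relation <- match.arg(relation, paste0("MR", 1:6))
  if (relation == "MR6") {
    if (!is(x, "EmbeddedDataset"))
      stop("MR6 applies to an EmbeddedDataset, not ", class(x)[1L])
    b <- dimBounds(x)
    return(EmbeddedDataset(-coords(x), cellIds = cellIds(x),
                           dimBounds = cbind(lo = -b[, 2L], hi = -b[, 1L]),
                           metadata = metadata(x)))
  }
  if (is(x, "EmbeddedDataset"))
    stop(relation, " applies to a count matrix, not an EmbeddedDataset")
  m <- .getCounts(x)
  set.seed(as.integer(seed))
  switch(relation,
    MR1 = {
      perm <- sample.int(ncol(m))
      .rebuildSCE(m[, perm, drop = FALSE], template = x, cellIdx = perm)
    },
    MR2 = {
      gene <- sample.int(nrow(m), 1L)
      m[gene, ] <- round(m[gene, ] * factor)
      .rebuildSCE(m, template = x, cellIdx = seq_len(ncol(m)))
    },
    MR3 = {
      cell <- sample.int(ncol(m), 1L)
      dup <- m[, cell, drop = FALSE]
      colnames(dup) <- paste0(colnames(m)[cell], "_dup")
      .rebuildSCE(cbind(m, dup), template = x,
                  cellIdx = c(seq_len(ncol(m)), cell))
    },
    MR4 = {
      perm <- sample.int(nrow(m))
      .rebuildSCE(m[perm, , drop = FALSE], template = x,
                  cellIdx = seq_len(ncol(m)))
    },
    MR5 = {
      pseudo <- matrix(as.numeric(value), nrow = 1L, ncol = ncol(m),
                       dimnames = list("pseudo_gene_constant",
                                       colnames(m)))
      .rebuildSCE(rbind(m, pseudo), template = x,
                  cellIdx = seq_len(ncol(m)))
    })
}

#' Metamorphic stability test
#'
#' Repeated-run stability harness: for each metamorphic relation, the
#' dataset is perturbed once and the supplied clusterer is run `repeats`
#' times with distinct seeds on both the original and the perturbed data.
#' The per-repeat silhouette scores form paired distributions compared by
#' a paired t-test; a relation is judged stable when `p > alpha` (no
#' detectable shift). When the paired differences have zero variance
#' (identical distributions) the relation is flagged degenerate and `p` is
#' reported as 1.
#'
#' @param x the dataset handed to `clusterer`: a count container for
#'   MR1-MR5 or an [EmbeddedDataset-class] for MR6.
#' @param clusterer `function(data, seed)` returning the (best-of-run)
#'   silhouette of a clustering of `data`; e.g. a wrapper around
#'   [preprocessCounts()] plus [runMOGA()].
#' @param relations character vector of relations to test.
#' @param repeats paired runs per relation (default 30).
#' @param alpha significance level (default 0.05).
#' @param seed base seed; run `r` uses `seed + r`.
#' @param ... passed to [applyMetamorphic()] (e.g. `factor` for MR2).
#' @return A [StabilityReport-class].
#' @export
stabilityTest <- function(x, clusterer, relations = paste0("MR", 1:6),
                          repeats = 30L, alpha = 0.05, seed = 1L, ...) {
  repeats <- as.integer(repeats)
  if (repeats < 2L) stop("'repeats' must be at least 2")
  runSeeds <- as.integer(seed) + seq_len(repeats)
  original <- vapply(runSeeds, function(s) clusterer(x, s), numeric(1))
  rows <- list(); dists <- list()
  for (rel in relations) {
    pert <- applyMetamorphic(x, rel, seed = seed, ...)
    perturbed <- vapply(runSeeds, function(s) clusterer(pert, s),
                        numeric(1))
    diffs <- perturbed - original
    degenerate <- stats::sd(diffs) <= .Machine$double.eps^0.5
    tt <- if (degenerate) NULL else
      tryCatch(stats::t.test(perturbed, original, paired = TRUE),
               error = function(e) NULL)
    if (is.null(tt)) {
      degenerate <- TRUE; tstat <- NA_real_; p <- 1
    } else {
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    rows[[rel]] <- data.frame(
      relation = rel, meanOriginal = mean(original),
      meanPerturbed = mean(perturbed), t = tstat, p = p,
      stable = p > alpha, degenerate = degenerate)
    dists[[rel]] <- cbind(original = original, perturbed = perturbed)
  }
  new("StabilityReport", table = do.call(rbind, c(rows, make.row.names = FALSE)),
      distributions = dists, alpha = alpha, repeats = repeats)
}

#' Default MOGA clusterer for the stability harness
#'
#' Builds a `function(data, seed)` suitable for [stabilityTest()]: count
#' input is preprocessed (with the reducer seeded by the run seed) and
#' clustered by [runMOGA()]; embedded input is clustered directly. The
#' returned value is the silhouette of the final solution.
#'
#' @param k number of clusters.
#' @param gaConfig a [GAConfig-class] template (its seed is replaced by
#'   the run seed).
#' @param preConfig a [PreprocessConfig-class] used for count input.
#' @return A clusterer function.
#' @export
mogaClusterer <- function(k,
                          gaConfig = mogaclust::gaConfig(
                            k = k, populationSize = 100, generations = 50),
                          preConfig = preprocessConfig(reducer = "pca")) {
  force(k); force(gaConfig); force(preConfig)
  function(data, seed) {
    ed <- if (is(data, "EmbeddedDataset")) {
      data
    } else {
      pc <- preConfig
      pc@seed <- as.integer(seed)
      preprocessCounts(data, pc)
    }
    cfg <- gaConfig
    cfg@seed <- as.integer(seed)
    res <- runMOGA(ed, cfg)
    res@report@sil
  }
}
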