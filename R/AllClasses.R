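#' @import methods
NULL

#' EmbeddedDataset: cells in a low-dimensional embedding
#'
#' Container for the reduced coordinates on which prototype-based clustering
#' operates. Rows are cells, columns are embedding dimensions (2 by default
#' after UMAP/PCA reduction). Per-dimension bounds delimit the search space
#' in which chromosomes are initialized and mutated.
#'
#' @slot coords numeric matrix, n cells x d dimensions; all entries finite.
#' @slot cellIds character vector of length n; unique cell identifiers.
#' @slot dimBounds numeric matrix, d x 2 (columns `lo`, `hi`), covering the
#'   coordinate range of every dimension.
#' @slot metadata list of provenance details (filter log, selected genes,
#'   per-PC explained variance, ...), accessible via
#'   [S4Vectors::metadata()].
#'
#' @seealso [EmbeddedDataset()], [reduceDimensions()], [assignClusters()]
#' @export
setClass("EmbeddedDataset",
  representation(
    coords = "matrix",
    cellIds = "character",
    dimBounds = "matrix",
    metadata = "list"
  )
)

setValidity("EmbeddedDataset", function(object) {
  msg <- character()
  x <- object@coords
  if (!is.numeric(x) || nrow(x) < 1L || ncol(x) < 1L)
    msg <- c(msg, "'coords' must be a non-empty numeric matrix")
  else if (!all(is.finite(x)))
    msg <- c(msg, "'coords' must be finite")
  if (length(object@cellIds) != nrow(x))
    msg <- c(msg, "'cellIds' length must equal nrow(coords)")
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "'cellIds' must be unique")
  b <- object@dimBounds
  if (!is.numeric(b) || nrow(b) != ncol(x) || ncol(b) != 2L)
    msg <- c(msg, "'dimBounds' must be a d x 2 numeric matrix")
  else if (is.numeric(x) && all(is.finite(x))) {
    lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
    if (any(b[, 1L] > lo + 1e-12) || any(b[, 2L] < hi - 1e-12))
      msg <- c(msg, "'dimBounds' must cover the coordinate range")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EmbeddedDataset
#'
#' @param coords numeric matrix of embedded coordinates (cells x dimensions).
#' @param cellIds character identifiers, one per cell; defaults to the row
#'   names of `coords` or `cell_1 ... cell_n`.
#' @param dimBounds optional d x 2 matrix of per-dimension (lo, hi) bounds;
#'   defaults to the observed coordinate range.
#' @return An [EmbeddedDataset-class] object.
#' @examples
#' ed <- EmbeddedDataset(matrix(rnorm(20), ncol = 2))
#' dim(coords(ed))
#' @export
EmbeddedDataset <- function(coords, cellIds = NULL, dimBounds = NULL,
                            metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(cellIds)) {
    cellIds <- rownames(coords)
    if (is.null(cellIds)) cellIds <- paste0("cell_", seq_len(nrow(coords)))
  }
  if (is.null(dimBounds)) {
    dimBounds <- cbind(lo = apply(coords, 2L, min),
                       hi = apply(coords, 2L, max))
  }
  dimBounds <- as.matrix(dimBounds)
  colnames(dimBounds) <- c("lo", "hi")
  rownames(coords) <- cellIds
  new("EmbeddedDataset", coords = coords, cellIds = as.character(cellIds),
      dimBounds = dimBounds, metadata = metadata)
}

#' ClusterAssignment: hard cluster memberships
#'
#' Labels induced by nearest-prototype assignment. Labels are integers in
#' `1..k`; empty clusters are permitted (a cluster index may receive no
#' cells), which matters during evolution where degenerate chromosomes can
#' leave prototypes unused.
#'
#' @slot labels integer vector of cluster labels in `1..k`.
#' @slot k integer, the number of prototypes (>= number of distinct labels).
#' @seealso [assignClusters()], [clusterSizes()]
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", k = "integer")
)

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "'k' must be a single positive integer")
  if (length(object@labels) < 1L)
    msg <- c(msg, "'labels' must be non-empty")
  if (anyNA(object@labels) ||
      (length(object@k) == 1L && !is.na(object@k) &&
       (any(object@labels < 1L) || any(object@labels > object@k))))
    msg <- c(msg, "'labels' must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterAssignment
#'
#' @param labels integer (or factor) labels, one per cell.
#' @param k number of clusters; defaults to `max(labels)`.
#' @return A [ClusterAssignment-class] object.
#' @export
ClusterAssignment <- function(labels, k = NULL) {
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (is.null(k)) k <- max(labels)
  new("ClusterAssignment", labels = labels, k = as.integer(k))
}

#' GAConfig: evolutionary-run configuration
#'
#' Hyperparameters of the genetic optimizer. The defaults for the variation
#' operators come from a grid search on a large reference transcriptome:
#' crossover probability 0.8, per-gene mutation probability 0.07, individual
#' mutation rate 1.0 and polynomial-mutation distribution index (eta) 0.3.
#' Tournaments draw 20% of the population.
#'
#' @slot populationSize even positive integer (default 800).
#' @slot generations positive integer (default 350).
#' @slot crossoverProb probability a parent pair is recombined.
#' @slot individualMutationRate probability an offspring is eligible for
#'   mutation at all.
#' @slot geneMutationProb per-position mutation probability.
#' @slot mutationEta distribution index of bounded polynomial mutation;
#'   small values produce offspring far from the parent.
#' @slot tournamentFraction fraction of the population entering each
#'   tournament.
#' @slot k number of cluster prototypes to evolve.
#' @slot seed integer seed owned by the run.
#' @slot workers number of parallel workers for fitness evaluation; fitness
#'   evaluation consumes no randomness, so results are identical for any
#'   worker count.
#' @seealso [gaConfig()], [runMOGA()], [runSOGA()]
#' @export
setClass("GAConfig",
  representation(
    populationSize = "integer",
    generations = "integer",
    crossoverProb = "numeric",
    individualMutationRate = "numeric",
    geneMutationProb = "numeric",
    mutationEta = "numeric",
    tournamentFraction = "numeric",
    k = "integer",
    seed = "integer",
    workers = "integer"
  )
)

setValidity("GAConfig", function(object) {
  msg <- character()
  p1 <- function(x) length(x) == 1L && !is.na(x)
  if (!p1(object@populationSize) || object@populationSize < 2L ||
      object@populationSize %% 2L != 0L)
    msg <- c(msg, "'populationSize' must be a positive even integer")
  if (!p1(object@generations) || object@generations < 1L)
    msg <- c(msg, "'generations' must be a positive integer")
  for (nm in c("crossoverProb", "individualMutationRate", "geneMutationProb")) {
    v <- slot(object, nm)
    if (!p1(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be in [0, 1]", nm))
  }
  if (!p1(object@mutationEta) || object@mutationEta <= 0)
    msg <- c(msg, "'mutationEta' must be positive")
  if (!p1(object@tournamentFraction) || object@tournamentFraction <= 0 ||
      object@tournamentFraction > 1)
    msg <- c(msg, "'tournamentFraction' must be in (0, 1]")
  if (!p1(object@k) || object@k < 1L)
    msg <- c(msg, "'k' must be a positive integer")
  if (!p1(object@workers) || object@workers < 1L)
    msg <- c(msg, "'workers' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a GAConfig
#'
#' @param k number of cluster prototypes.
#' @param populationSize population size; rounded up to an even number so
#'   that mating pairs are total (default 800).
#' @param generations number of generations (default 350; the optimizer
#'   typically converges after about 50).
#' @param crossoverProb one-point crossover probability (default 0.8).
#' @param individualMutationRate probability an offspring undergoes mutation
#'   (default 1.0).
#' @param geneMutationProb per-gene mutation probability (default 0.07).
#' @param mutationEta polynomial-mutation distribution index (default 0.3).
#' @param tournamentFraction tournament size as a fraction of the population
#'   (default 0.2).
#' @param seed integer seed (default 1).
#' @param workers parallel workers for fitness evaluation (default 1).
#' @return A [GAConfig-class] object.
#' @examples
#' cfg <- gaConfig(k = 4, populationSize = 100, generations = 50)
#' @export
gaConfig <- function(k, populationSize = 800L, generations = 350L,
                     crossoverProb = 0.8, individualMutationRate = 1.0,
                     geneMutationProb = 0.07, mutationEta = 0.3,
                     tournamentFraction = 0.2, seed = 1L, workers = 1L) {
  populationSize <- as.integer(ceiling(populationSize / 2) * 2)
  new("GAConfig",
      populationSize = populationSize,
      generations = as.integer(generations),
      crossoverProb = as.numeric(crossoverProb),
      individualMutationRate = as.numeric(individualMutationRate),
      geneMutationProb = as.numeric(geneMutationProb),
      mutationEta = as.numeric(mutationEta),
      tournamentFraction = as.numeric(tournamentFraction),
      k = as.integer(k), seed = as.integer(seed),
      workers = as.integer(workers))
}

#' ParetoFront: the non-dominated solutions of a finished run
#'
#' Rank-0 chromosomes of the final generation together with their objective
#' pairs: `f1` (weighted prototype separation, maximized) and `f2` (total
#' within-cluster distance, minimized). No member dominates another.
#'
#' @slot genes numeric matrix, one chromosome per row (length k*d each).
#' @slot objectives numeric matrix with columns `f1`, `f2`.
#' @slot k number of prototypes per chromosome.
#' @slot d embedding dimensionality.
#' @seealso [runMOGA()], [selectFinalSolution()]
#' @export
setClass("ParetoFront",
  representation(genes = "matrix", objectives = "matrix",
                 k = "integer", d = "integer")
)

setValidity("ParetoFront", function(object) {
  msg <- character()
  if (nrow(object@genes) < 1L)
    msg <- c(msg, "front must be non-empty")
  if (nrow(object@genes) != nrow(object@objectives))
    msg <- c(msg, "'genes' and 'objectives' must have matching rows")
  if (ncol(object@objectives) != 2L)
    msg <- c(msg, "'objectives' must have two columns (f1, f2)")
  if (ncol(object@genes) != object@k * object@d)
    msg <- c(msg, "chromosome length must equal k * d")
  if (length(msg)) msg else TRUE
})

#' ValidityReport: cluster-validity metrics for one solution
#'
#' @slot sil mean silhouette width, in `[-1, 1]`.
#' @slot nmi normalized mutual information vs. reference labels, in
#'   `[0, 1]`; `NA` when no reference labels were supplied.
#' @slot ari adjusted Rand index vs. reference labels (can be slightly
#'   negative for worse-than-chance partitions); `NA` without reference.
#' @slot dbi Davies-Bouldin index (non-negative; `Inf` when fewer than two
#'   clusters are populated).
#' @seealso [validityReport()]
#' @export
setClass("ValidityReport",
  representation(sil = "numeric", nmi = "numeric",
                 ari = "numeric", dbi = "numeric")
)

#' MOGAResult: output of a multi-objective clustering run
#'
#' @slot front the final [ParetoFront-class].
#' @slot chromosome the DBI-selected final chromosome.
#' @slot assignment the induced [ClusterAssignment-class].
#' @slot report internal validity of the final solution.
#' @slot history per-generation log (generation, best f1, best f2, front
#'   size).
#' @slot config the [GAConfig-class] used.
#' @export
setClass("MOGAResult",
  representation(front = "ParetoFront", chromosome = "numeric",
                 assignment = "ClusterAssignment", report = "ValidityReport",
                 history = "data.frame", config = "GAConfig")
)

#' SOGAResult: output of the single-objective baseline
#'
#' @slot chromosome the best chromosome of the final generation.
#' @slot assignment the induced [ClusterAssignment-class].
#' @slot f2 compactness objective of the returned chromosome.
#' @slot history per-generation best-f2 log.
#' @slot config the [GAConfig-class] used.
#' @export
setClass("SOGAResult",
  representation(chromosome = "numeric", assignment = "ClusterAssignment",
                 f2 = "numeric", history = "data.frame", config = "GAConfig")
)

#' PreprocessConfig: parameters of the preprocessing workflow
#'
#' Defaults follow the standard single-cell workflow: cells with fewer than
#' 200 expressed genes and genes expressed in fewer than 3 cells are
#' removed; cells with mitochondrial content above 10% are removed; per-cell
#' totals are bounded by `10^(mean(log10 x) +/- 2 sd(log10 x))`; the top
#' 2000 highly variable genes are kept; data are reduced to 10 principal
#' components and then to a 2-D embedding.
#'
#' @slot minGenesPerCell minimum expressed genes per retained cell.
#' @slot minCellsPerGene minimum cells expressing a retained gene.
#' @slot maxMitoFraction maximum mitochondrial count fraction per cell.
#' @slot outlierSD half-width, in standard deviations of log10 totals, of
#'   the per-cell outlier bounds.
#' @slot nHVG number of highly variable genes to keep.
#' @slot nPCs number of principal components.
#' @slot embedDims dimensionality of the final embedding.
#' @slot mitoPrefix case-insensitive gene-id prefix marking mitochondrial
#'   genes.
#' @slot reducer final reducer: `"umap"` (nonlinear neighbor embedding) or
#'   `"pca"` (first `embedDims` principal components; exactly
#'   deterministic).
#' @slot seed seed for the nonlinear reducer.
#' @seealso [preprocessConfig()], [preprocessCounts()]
#' @export
setClass("PreprocessConfig",
  representation(
    minGenesPerCell = "integer", minCellsPerGene = "integer",
    maxMitoFraction = "numeric", outlierSD = "numeric",
    nHVG = "integer", nPCs = "integer", embedDims = "integer",
    mitoPrefix = "character", reducer = "character", seed = "integer"
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@minGenesPerCell < 0L || object@minCellsPerGene < 0L)
    msg <- c(msg, "filter thresholds must be non-negative")
  if (object@maxMitoFraction < 0 || object@maxMitoFraction > 1)
    msg <- c(msg, "'maxMitoFraction' must be in [0, 1]")
  if (object@outlierSD <= 0)
    msg <- c(msg, "'outlierSD' must be positive")
  if (object@nHVG < 1L || object@nPCs < 1L || object@embedDims < 1L)
    msg <- c(msg, "'nHVG', 'nPCs' and 'embedDims' must be positive")
  if (object@embedDims > object@nPCs)
    msg <- c(msg, "'embedDims' must not exceed 'nPCs'")
  if (!object@reducer %in% c("umap", "pca"))
    msg <- c(msg, "'reducer' must be 'umap' or 'pca'")
  if (length(msg)) msg else TRUE
})

#' Construct a PreprocessConfig
#'
#' @param minGenesPerCell,minCellsPerGene,maxMitoFraction,outlierSD,nHVG,nPCs,embedDims,mitoPrefix,reducer,seed
#'   see [PreprocessConfig-class].
#' @return A [PreprocessConfig-class] object.
#' @examples
#' preprocessConfig(reducer = "pca")
#' @export
preprocessConfig <- function(minGenesPerCell = 200L, minCellsPerGene = 3L,
                             maxMitoFraction = 0.10, outlierSD = 2.0,
                             nHVG = 2000L, nPCs = 10L, embedDims = 2L,
                             mitoPrefix = "MT-", reducer = "umap",
                             seed = 1L) {
  new("PreprocessConfig",
      minGenesPerCell = as.integer(minGenesPerCell),
      minCellsPerGene = as.integer(minCellsPerGene),
      maxMitoFraction = as.numeric(maxMitoFraction),
      outlierSD = as.numeric(outlierSD),
      nHVG = as.integer(nHVG), nPCs = as.integer(nPCs),
      embedDims = as.integer(embedDims),
      mitoPrefix = as.character(mitoPrefix),
      reducer = match.arg(reducer, c("umap", "pca")),
      seed = as.integer(seed))
}

#' SimulationConfig: parameters of the grouped count simulator
#'
#' Hierarchical gamma-Poisson generative model of grouped scRNA-seq counts:
#' gene base means are Gamma distributed, a fraction of genes per group
#' receives log-normal differential-expression multipliers, cell library
#' sizes are log-normal, and counts are Poisson around the library-scaled
#' group expression profile.
#'
#' @slot nCells number of cells.
#' @slot nGenes number of genes.
#' @slot nGroups number of cell groups.
#' @slot groupProbs group membership probabilities (sums to 1).
#' @slot deProb fraction of genes differentially expressed per group.
#' @slot deFactorLocation,deFactorScale meanlog/sdlog of the log-normal DE
#'   multipliers (applied up- or down-regulated with equal probability).
#' @slot libLocation,libScale meanlog/sdlog of log-normal library sizes.
#' @slot geneMeanShape,geneMeanRate Gamma hyperparameters of gene base
#'   means.
#' @slot seed integer seed.
#' @seealso [simulationConfig()], [simulateCounts()]
#' @export
setClass("SimulationConfig",
  representation(
    nCells = "integer", nGenes = "integer", nGroups = "integer",
    groupProbs = "numeric", deProb = "numeric",
    deFactorLocation = "numeric", deFactorScale = "numeric",
    libLocation = "numeric", libScale = "numeric",
    geneMeanShape = "numeric", geneMeanRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nCells < 1L || object@nGenes < 1L || object@nGroups < 1L)
    msg <- c(msg, "'nCells', 'nGenes', 'nGroups' must be positive")
  if (object@nGroups > object@nCells)
    msg <- c(msg, "'nGroups' must not exceed 'nCells'")
  if (length(object@groupProbs) != object@nGroups ||
      any(object@groupProbs < 0) ||
      abs(sum(object@groupProbs) - 1) > 1e-8)
    msg <- c(msg, "'groupProbs' must be a probability vector of length nGroups")
  if (object@deProb < 0 || object@deProb > 1)
    msg <- c(msg, "'deProb' must be in [0, 1]")
  if (object@deFactorScale < 0 || object@libScale < 0)
    msg <- c(msg, "scale parameters must be non-negative")
  if (object@geneMeanShape <= 0 || object@geneMeanRate <= 0)
    msg <- c(msg, "gamma hyperparameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nCells,nGenes,nGroups,groupProbs,deProb,deFactorLocation,deFactorScale,libLocation,libScale,geneMeanShape,geneMeanRate,seed
#'   see [SimulationConfig-class].
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nCells = 200, nGroups = 4, seed = 7)
#' @export
simulationConfig <- function(nCells = 1000L, nGenes = 2000L, nGroups = 2L,
                             groupProbs = NULL, deProb = 0.1,
                             deFactorLocation = 1.2, deFactorScale = 0.3,
                             libLocation = log(10000), libScale = 0.25,
                             geneMeanShape = 0.6, geneMeanRate = 0.3,
                             seed = 1L) {
  if (is.null(groupProbs)) groupProbs <- rep(1 / nGroups, nGroups)
  new("SimulationConfig",
      nCells = as.integer(nCells), nGenes = as.integer(nGenes),
      nGroups = as.integer(nGroups), groupProbs = as.numeric(groupProbs),
      deProb = as.numeric(deProb),
      deFactorLocation = as.numeric(deFactorLocation),
      deFactorScale = as.numeric(deFactorScale),
      libLocation = as.numeric(libLocation), libScale = as.numeric(libScale),
      geneMeanShape = as.numeric(geneMeanShape),
      geneMeanRate = as.numeric(geneMeanRate),
      seed = as.integer(seed))
}

#' StabilityReport: metamorphic stability results
#'
#' One row per metamorphic relation: the paired t statistic and p-value
#' comparing the silhouette distribution on perturbed data against the
#' original, and a verdict (`stable` if p > alpha). A degenerate flag marks
#' relations where the paired differences had zero variance (identical
#' distributions), for which p is reported as 1.
#'
#' @slot table data.frame with columns `relation`, `meanOriginal`,
#'   `meanPerturbed`, `t`, `p`, `stable`, `degenerate`.
#' @slot distributions named list of per-relation matrices (columns
#'   `original`, `perturbed`, one row per repeat).
#' @slot alpha significance level.
#' @slot repeats repeats per relation.
#' @seealso [stabilityTest()]
#' @export
setClass("StabilityReport",
  representation(table = "data.frame", distributions = "list",
                 alpha = "numeric", repeats = "integer")
)

#' RuntimeModel: ensemble-of-trees run-time estimator
#'
#' @slot fit fitted randomForest regressor.
#' @slot features feature names used by the model.
#' @slot seed seed used at fit time.
#' @seealso [fitRuntimeModel()], [predictRuntime()]
#' @export
setClass("RuntimeModel",
  representation(fit = "ANY", features = "character", seed = "integer")
)
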