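#' Accessors for mogaclust classes
#'
#' Small accessor generics: `coords()` and `cellIds()` read the embedding
#' matrix and cell identifiers of an [EmbeddedDataset-class]; `dimBounds()`
#' its per-dimension bounds; `clusterLabels()` and `clusterSizes()` read a
#' [ClusterAssignment-class]; `nClusters()` the number of prototypes;
#' `prototypes()` the decoded prototype matrix of a result; `paretoFront()`
#' the final front of a [MOGAResult-class]; `objectivePairs()` its (f1, f2)
#' matrix.
#'
#' @param x an object of the documented class.
#' @return The accessed component.
#' @name accessors
#' @aliases coords cellIds dimBounds clusterLabels clusterSizes nClusters
#'   prototypes paretoFront objectivePairs
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("dimBounds", function(x) standardGeneric("dimBounds"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))
#' @rdname accessors
#' @export
setGeneric("paretoFront", function(x) standardGeneric("paretoFront"))
#' @rdname accessors
#' @export
setGeneric("objectivePairs", function(x) standardGeneric("objectivePairs"))

#' @rdname accessors
setMethod("coords", "EmbeddedDataset", function(x) x@coords)
#' @rdname accessors
setMethod("cellIds", "EmbeddedDataset", function(x) x@cellIds)
#' @rdname accessors
setMethod("dimBounds", "EmbeddedDataset", function(x) x@dimBounds)

#' @rdname accessors
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)
#' @rdname accessors
setMethod("clusterSizes", "ClusterAssignment",
          function(x) tabulate(x@labels, x@k))
#' @rdname accessors
setMethod("nClusters", "ClusterAssignment", function(x) x@k)

#' @rdname accessors
setMethod("clusterLabels", "MOGAResult", function(x) x@assignment@labels)
#' @rdname accessors
setMethod("clusterLabels", "SOGAResult", function(x) x@assignment@labels)
#' @rdname accessors
setMethod("paretoFront", "MOGAResult", function(x) x@front)
#' @rdname accessors
setMethod("objectivePairs", "ParetoFront", function(x) x@objectives)
#' @rdname accessors
setMethod("prototypes", "MOGAResult",
          function(x) decodeChromosome(x@chromosome, x@config@k,
                                       x@front@d))
#' @rdname accessors
setMethod("prototypes", "SOGAResult",
          function(x) decodeChromosome(x@chromosome, x@config@k,
                                       length(x@chromosome) %/% x@config@k))

#' @rdname accessors
#' @importFrom S4Vectors metadata
#' @export
setMethod("metadata", "EmbeddedDataset", function(x, ...) x@metadata)

setMethod("show", "EmbeddedDataset", function(object) {
  cat(sprintf("EmbeddedDataset: %d cells x %d dimensions\n",
              nrow(object@coords), ncol(object@coords)))
  b <- object@dimBounds
  for (j in seq_len(nrow(b)))
    cat(sprintf("  dim %d bounds: [%.4g, %.4g]\n", j, b[j, 1], b[j, 2]))
})

setMethod("show", "ClusterAssignment", function(object) {
  cs <- tabulate(object@labels, object@k)
  cat(sprintf("ClusterAssignment: %d cells, k = %d (%d populated)\n",
              length(object@labels), object@k, sum(cs > 0L)))
  cat("  sizes:", paste(cs, collapse = " "), "\n")
})

setMethod("show", "ParetoFront", function(object) {
  cat(sprintf("ParetoFront: %d non-dominated solutions (k = %d, d = %d)\n",
              nrow(object@genes), object@k, object@d))
  rng <- apply(object@objectives, 2L, range)
  cat(sprintf("  f1 (separation, max): %.4g .. %.4g\n", rng[1, 1], rng[2, 1]))
  cat(sprintf("  f2 (compactness, min): %.4g .. %.4g\n", rng[1, 2], rng[2, 2]))
})

setMethod("show", "ValidityReport", function(object) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("ValidityReport:\n",
      "  sil =", fmt(object@sil), "\n",
      "  nmi =", fmt(object@nmi), "\n",
      "  ari =", fmt(object@ari), "\n",
      "  dbi =", fmt(object@dbi), "\n")
})

setMethod("show", "MOGAResult", function(object) {
  cat(sprintf("MOGAResult: k = %d, %d cells\n",
              object@config@k, length(object@assignment@labels)))
  cat(sprintf("  front size: %d\n", nrow(object@front@genes)))
  show(object@report)
})

setMethod("show", "SOGAResult", function(object) {
  cat(sprintf("SOGAResult: k = %d, %d cells, best f2 = %.4g\n",
              object@config@k, length(object@assignment@labels), object@f2))
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d relations, %d repeats, alpha = %g\n",
              nrow(object@table), object@repeats, object@alpha))
  print(object@table, row.names = FALSE)
})

setMethod("show", "GAConfig", function(object) {
  cat(sprintf(paste0(
    "GAConfig: k = %d, pop = %d, generations = %d\n",
    "  cx = %.2f, indpb(mut) = %.2f, genepb = %.2f, eta = %.2f,",
    " tournament = %.2f\n  seed = %d, workers = %d\n"),
    object@k, object@populationSize, object@generations,
    object@crossoverProb, object@individualMutationRate,
    object@geneMutationProb, object@mutationEta,
    object@tournamentFraction, object@seed, object@workers))
})
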