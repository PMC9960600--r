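#' Mean silhouette width
#'
#' Internal validity of a hard clustering on the embedded coordinates. For
#' each cell, `a` is its mean Euclidean distance to the other cells of its
#' cluster and `b` the minimum over other populated clusters of its mean
#' distance to that cluster's cells; the silhouette is
#' `s = (b - a) / max(a, b)`. A cell that is the sole member of its cluster
#' contributes exactly 0. The return value is the mean over all cells,
#' in `[-1, 1]`.
#'
#' @param data an [EmbeddedDataset-class], or a precomputed symmetric
#'   distance matrix.
#' @param assignment a [ClusterAssignment-class] or an integer/factor label
#'   vector.
#' @param perCell return the per-cell silhouette values instead of their
#'   mean.
#' @return Scalar mean silhouette width, or a numeric vector when
#'   `perCell = TRUE`.
#' @examples
#' ed <- EmbeddedDataset(rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1)))
#' silhouetteWidth(ed, c(1, 1, 2, 2))
#' @export
silhouetteWidth <- function(data, assignment, perCell = FALSE) {
  D <- if (is(data, "EmbeddedDataset")) {
    as.matrix(stats::dist(coords(data)))
  } else {
    as.matrix(data)
  }
  labels <- if (is(assignment, "ClusterAssignment")) {
    clusterLabels(assignment)
  } else {
    as.integer(as.factor(assignment))
  }
  n <- length(labels)
  if (nrow(D) != n) stop("labels do not match the number of cells")
  k <- max(labels)
  counts <- tabulate(labels, k)
  populated <- which(counts > 0L)
  if (length(populated) < 2L)
    stop("silhouette requires at least two populated clusters")
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sums <- D %*% ind                       # n x k total distance to cluster
  own <- counts[labels]
  a <- ifelse(own > 1L, sums[cbind(seq_len(n), labels)] / (own - 1L), 0)
  meanOther <- sweep(sums, 2L, pmax(counts, 1L), "/")
  meanOther[, counts == 0L] <- Inf
  meanOther[cbind(seq_len(n), labels)] <- Inf
  b <- apply(meanOther, 1L, min)
  s <- ifelse(own == 1L, 0, (b - a) / pmax(a, b))
  s[own > 1L & pmax(a, b) == 0] <- 0   # coincident points
  if (perCell) s else mean(s)
}

#' Contingency table of two label vectors
#'
#' Cross-tabulation `n_ij`: the number of cells carrying label `i` in the
#' first vector and label `j` in the second, the shared basis of the NMI
#' and ARI external validity metrics.
#'
#' @param labelsA,labelsB equal-length label vectors (integer, character or
#'   factor).
#' @return Integer matrix with row/column names taken from the label
#'   values.
#' @export
contingencyTable <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  unclass(table(labelsA, labelsB, dnn = NULL))
}

#' Normalized mutual information of two partitions
#'
#' `NMI = 2 I(A; B) / (H(A) + H(B))` with entropies in bits. By convention
#' two single-cluster (zero-entropy) partitions agree perfectly (NMI 1),
#' while a single-cluster partition against a non-trivial one shares no
#' information (NMI 0). Symmetric, invariant to label renaming, in
#' `[0, 1]`.
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @return Scalar in `[0, 1]`.
#' @examples
#' nmi(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1: identical up to renaming
#' nmi(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0: independent
#' @export
nmi <- function(labelsA, labelsB) {
  tab <- contingencyTable(labelsA, labelsB)
  n <- sum(tab)
  if (n < 1L) stop("empty label vectors")
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hA <- ent(pi); hB <- ent(pj)
  if (hA == 0 && hB == 0) return(1)
  if (hA == 0 || hB == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log2(pij[nz] / (pi[row(pij)[nz]] * pj[col(pij)[nz]])))
  2 * mi / (hA + hB)
}

#' Adjusted Rand index of two partitions
#'
#' Pair-counting agreement between two partitions, corrected for chance
#' from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` where
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `max = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`.
#' Equals 1 iff the partitions are identical up to renaming; the expected
#' value under independent random partitions is 0, and worse-than-chance
#' partitions can give small negative values (no clamping is applied).
#'
#' @param labelsA,labelsB equal-length label vectors, length >= 2.
#' @return Scalar, at most 1.
#' @export
ari <- function(labelsA, labelsB) {
  tab <- contingencyTable(labelsA, labelsB)
  n <- sum(tab)
  if (n < 2L) stop("ARI needs at least two cells")
  ch2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(ch2(tab))
  sumA <- sum(ch2(rowSums(tab)))
  sumB <- sum(ch2(colSums(tab)))
  expected <- sumA * sumB / ch2(n)
  maxIndex <- (sumA + sumB) / 2
  if (maxIndex == expected) return(1)  # both partitions trivial
  (sumIJ - expected) / (maxIndex - expected)
}

#' Cluster-validity report for one solution
#'
#' Bundles internal validity (silhouette and, when prototypes are given,
#' the Davies-Bouldin index) and, when reference labels are given,
#' external validity (NMI and ARI) into one [ValidityReport-class].
#'
#' @param data an [EmbeddedDataset-class].
#' @param assignment a [ClusterAssignment-class] or label vector.
#' @param truth optional reference labels for external validation.
#' @param prototypes optional `k x d` prototype matrix for the
#'   Davies-Bouldin index.
#' @return A [ValidityReport-class].
#' @export
validityReport <- function(data, assignment, truth = NULL,
                           prototypes = NULL) {
  if (!is(assignment, "ClusterAssignment"))
    assignment <- ClusterAssignment(assignment)
  sil <- tryCatch(silhouetteWidth(data, assignment),
                  error = function(e) NA_real_)
  dbi <- if (is.null(prototypes)) NA_real_ else
    daviesBouldin(data, prototypes, assignment)
  labels <- clusterLabels(assignment)
  new("ValidityReport",
      sil = sil,
      nmi = if (is.null(truth)) NA_real_ else nmi(labels, truth),
      ari = if (is.null(truth)) NA_real_ else ari(labels, truth),
      dbi = dbi)
}
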