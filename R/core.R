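#' Decode a chromosome into cluster prototypes
#'
#' A clustering solution is encoded as a flat real vector of length
#' `k * d`: the first `d` values are the prototype of cluster 1, the next
#' `d` values the prototype of cluster 2, and so on.
#'
#' @param genes numeric vector of length `k * d`.
#' @param k number of prototypes.
#' @param d embedding dimensionality.
#' @return A `k x d` numeric matrix, one prototype per row.
#' @examples
#' decodeChromosome(c(0, 0, 2, 0), k = 2, d = 2)
#' @seealso [encodePrototypes()], [assignClusters()]
#' @export
decodeChromosome <- function(genes, k, d) {
  genes <- as.numeric(genes)
  k <- as.integer(k); d <- as.integer(d)
  if (length(genes) != k * d)
    stop("chromosome length ", length(genes), " != k * d = ", k * d)
  matrix(genes, nrow = k, ncol = d, byrow = TRUE)
}

#' Encode prototypes as a chromosome
#'
#' Inverse of [decodeChromosome()]: rows of the prototype matrix are
#' concatenated into one flat vector.
#'
#' @param prototypes `k x d` numeric matrix.
#' @return Numeric vector of length `k * d`.
#' @export
encodePrototypes <- function(prototypes) {
  prototypes <- as.matrix(prototypes)
  as.numeric(t(prototypes))
}

## squared Euclidean distances between n x d points and k x d prototypes,
## returned as an n x k matrix. Uses the expansion |x - z|^2 =
## |x|^2 - 2 x.z + |z|^2; clamped at 0 against rounding.
.sqDistToPrototypes <- function(coords, prototypes) {
  d2 <- outer(rowSums(coords^2), rowSums(prototypes^2), "+") -
    2 * tcrossprod(coords, prototypes)
  d2[d2 < 0] <- 0
  d2
}

#' Assign cells to their nearest prototype
#'
#' Each cell receives the label of the prototype minimizing the Euclidean
#' distance; ties are broken deterministically in favor of the lowest
#' prototype index.
#'
#' @param data an [EmbeddedDataset-class].
#' @param prototypes `k x d` matrix of prototypes (or a chromosome decoded
#'   via [decodeChromosome()]).
#' @return A [ClusterAssignment-class] with labels in `1..k`; clusters may
#'   be empty.
#' @examples
#' ed <- EmbeddedDataset(matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE))
#' clusterLabels(assignClusters(ed, rbind(c(0, 0), c(9, 9))))
#' @export
assignClusters <- function(data, prototypes) {
  prototypes <- as.matrix(prototypes)
  x <- coords(data)
  if (ncol(prototypes) != ncol(x))
    stop("prototype dimension ", ncol(prototypes),
         " != data dimension ", ncol(x))
  d2 <- .sqDistToPrototypes(x, prototypes)
  labels <- max.col(-d2, ties.method = "first")
  ClusterAssignment(labels, k = nrow(prototypes))
}

#' Separation objective (maximized)
#'
#' The first clustering objective: the weighted sum, over clusters, of the
#' Euclidean distance between each cluster prototype and the unweighted
#' mean vector of all prototypes, weighted by cluster occupancy:
#' `f1 = sum_i n_i * d(z_i, z_bar)`. Larger values correspond to prototypes
#' that are well separated and well used; an empty cluster contributes
#' nothing. For `k = 1` the objective is identically 0.
#'
#' @param prototypes `k x d` prototype matrix.
#' @param assignment the [ClusterAssignment-class] induced by these
#'   prototypes.
#' @return Non-negative scalar.
#' @seealso [objectiveCompactness()]
#' @export
objectiveSeparation <- function(prototypes, assignment) {
  prototypes <- as.matrix(prototypes)
  k <- nrow(prototypes)
  if (k < 1L) stop("at least one prototype is required")
  if (nClusters(assignment) != k)
    stop("assignment was made for ", nClusters(assignment),
         " prototypes, not ", k)
  zbar <- colMeans(prototypes)
  dz <- sqrt(rowSums(sweep(prototypes, 2L, zbar)^2))
  sum(clusterSizes(assignment) * dz)
}

#' Compactness objective (minimized)
#'
#' The second clustering objective: the total sum of Euclidean distances
#' between each cell and the prototype of its cluster,
#' `f2 = sum_i sum_{x in c_i} d(x, z_i)`. Empty clusters contribute 0.
#'
#' @param data an [EmbeddedDataset-class].
#' @param prototypes `k x d` prototype matrix.
#' @param assignment the induced [ClusterAssignment-class].
#' @return Non-negative scalar.
#' @seealso [objectiveSeparation()]
#' @export
objectiveCompactness <- function(data, prototypes, assignment) {
  prototypes <- as.matrix(prototypes)
  x <- coords(data)
  if (ncol(prototypes) != ncol(x))
    stop("prototype dimension != data dimension")
  labels <- clusterLabels(assignment)
  diff <- x - prototypes[labels, , drop = FALSE]
  sum(sqrt(rowSums(diff^2)))
}

## One fitness evaluation: labels, f1 and f2 from a single distance matrix.
## Consumes no randomness (safe for parallel evaluation).
.evalChromosome <- function(coords, genes, k) {
  d <- ncol(coords)
  protos <- matrix(genes, nrow = k, ncol = d, byrow = TRUE)
  d2 <- .sqDistToPrototypes(coords, protos)
  labels <- max.col(-d2, ties.method = "first")
  nn <- sqrt(d2[cbind(seq_len(nrow(coords)), labels)])
  counts <- tabulate(labels, k)
  zbar <- colMeans(protos)
  dz <- sqrt(rowSums(sweep(protos, 2L, zbar)^2))
  list(f1 = sum(counts * dz), f2 = sum(nn), labels = labels)
}

#' Davies-Bouldin index of a prototype-based clustering
#'
#' Mean, over populated clusters, of the worst-case ratio between summed
#' within-cluster scatters and between-prototype distance:
#' `DBI = (1/k') sum_i max_{j != i} (S_i + S_j) / d(z_i, z_j)` where
#' `S_i` is the mean Euclidean distance of the cells of cluster `i` to its
#' prototype. Only the `k'` populated clusters enter the index; a singleton
#' cluster has `S_i = 0`. Lower values indicate better clusterings.
#'
#' @param data an [EmbeddedDataset-class].
#' @param prototypes `k x d` prototype matrix.
#' @param assignment the induced [ClusterAssignment-class].
#' @return Non-negative scalar; `Inf` when fewer than two clusters are
#'   populated (such a solution can never be preferred).
#' @seealso [selectFinalSolution()]
#' @export
daviesBouldin <- function(data, prototypes, assignment) {
  prototypes <- as.matrix(prototypes)
  x <- coords(data)
  labels <- clusterLabels(assignment)
  k <- nrow(prototypes)
  counts <- tabulate(labels, k)
  keep <- which(counts > 0L)
  if (length(keep) < 2L) return(Inf)
  diff <- x - prototypes[labels, , drop = FALSE]
  dcell <- sqrt(rowSums(diff^2))
  scatter <- as.numeric(rowsum(dcell, labels, reorder = TRUE))
  present <- sort(unique(labels))
  s <- numeric(k)
  s[present] <- scatter / counts[present]
  z <- prototypes[keep, , drop = FALSE]
  dz <- as.matrix(stats::dist(z))
  ratio <- outer(s[keep], s[keep], "+") / dz
  diag(ratio) <- -Inf
  mean(apply(ratio, 1L, max))
}
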