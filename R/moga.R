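#' Initialize a random population of prototype chromosomes
#'
#' Every gene is drawn uniformly within the bounds of its embedding
#' dimension (gene position `j` encodes dimension `((j - 1) mod d) + 1`).
#' Draws come from the session RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param data an [EmbeddedDataset-class]; its `dimBounds` delimit the
#'   sampling box.
#' @param config a [GAConfig-class] providing `populationSize` and `k`.
#' @return Numeric matrix, `populationSize` rows, each a chromosome of
#'   length `k * d`.
#' @export
initializePopulation <- function(data, config) {
  b <- dimBounds(data)
  d <- nrow(b)
  k <- config@k
  n <- config@populationSize
  l <- k * d
  lower <- rep(b[, 1L], times = k)
  upper <- rep(b[, 2L], times = k)
  pop <- matrix(stats::runif(n * l), nrow = n, byrow = TRUE)
  sweep(sweep(pop, 2L, upper - lower, "*"), 2L, lower, "+")
}

#' Pareto dominance between two objective pairs
#'
#' Solution `a` dominates `b` when it is no worse in both objectives and
#' strictly better in at least one, with the separation objective `f1`
#' maximized and the compactness objective `f2` minimized.
#'
#' @param a,b numeric length-2 vectors `(f1, f2)`.
#' @return `TRUE` if `a` dominates `b`.
#' @examples
#' dominates(c(2, 1), c(1, 2))  # TRUE
#' dominates(c(2, 2), c(1, 1))  # FALSE: trade-off, incomparable
#' @export
dominates <- function(a, b) {
  (a[1L] >= b[1L] && a[2L] <= b[2L]) && (a[1L] > b[1L] || a[2L] < b[2L])
}

## m x m logical matrix; [i, j] TRUE when solution i dominates solution j.
.dominationMatrix <- function(objectives) {
  f1 <- objectives[, 1L]; f2 <- objectives[, 2L]
  ge1 <- outer(f1, f1, ">="); le2 <- outer(f2, f2, "<=")
  gt1 <- outer(f1, f1, ">");  lt2 <- outer(f2, f2, "<")
  (ge1 & le2) & (gt1 | lt2)
}

#' Fast non-dominated sorting
#'
#' Partitions a set of objective pairs into Pareto fronts: front 1 holds
#' all solutions dominated by none, front 2 those dominated only by front
#' 1, and so on (f1 maximized, f2 minimized).
#'
#' @param objectives numeric matrix with columns `(f1, f2)`, one row per
#'   solution; all values finite.
#' @return List of integer vectors of row indices, one per front, jointly
#'   partitioning `1:nrow(objectives)`.
#' @examples
#' fastNonDominatedSort(rbind(c(2, 1), c(1, 2), c(1, 1)))
#' @export
fastNonDominatedSort <- function(objectives) {
  objectives <- as.matrix(objectives)
  m <- nrow(objectives)
  if (m == 0L) return(list())
  dom <- .dominationMatrix(objectives)
  count <- colSums(dom)
  fronts <- list()
  remaining <- rep(TRUE, m)
  while (any(remaining)) {
    cur <- which(remaining & count == 0L)
    fronts[[length(fronts) + 1L]] <- cur
    remaining[cur] <- FALSE
    if (any(remaining) && length(cur))
      count <- count - colSums(dom[cur, , drop = FALSE])
  }
  fronts
}

#' Crowding distance within one front
#'
#' NSGA-II diversity measure: per objective, solutions are sorted, boundary
#' solutions receive infinite distance, and interior solutions accumulate
#' the normalized gap between their sorted neighbors. Objectives with zero
#' range contribute nothing.
#'
#' @param objectives numeric matrix `(f1, f2)`, one row per front member.
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
crowdingDistance <- function(objectives) {
  objectives <- as.matrix(objectives)
  m <- nrow(objectives)
  if (m <= 2L) return(rep(Inf, m))
  cd <- numeric(m)
  for (j in seq_len(ncol(objectives))) {
    v <- objectives[, j]
    ord <- order(v)
    rng <- v[ord[m]] - v[ord[1L]]
    cd[ord[c(1L, m)]] <- Inf
    if (rng > 0) {
      mid <- ord[2:(m - 1L)]
      cd[mid] <- cd[mid] + (v[ord[3:m]] - v[ord[1:(m - 2L)]]) / rng
    }
  }
  cd
}

#' Tournament selection of breeding parents
#'
#' Repeatedly draws `ceiling(tournamentFraction * n)` distinct entrants
#' uniformly from the population and selects the winner: lowest
#' non-domination rank, then largest crowding distance, remaining ties
#' broken uniformly at random. Tournaments are repeated (with replacement
#' across tournaments) until `n` parents are selected.
#'
#' @param rank integer non-domination ranks (1 = non-dominated).
#' @param crowding crowding distances matching `rank`.
#' @param n number of parents to select (defaults to the population size).
#' @param tournamentFraction fraction of the population entering each
#'   tournament (default 0.2).
#' @return Integer vector of `n` selected population indices.
#' @export
tournamentSelect <- function(rank, crowding, n = length(rank),
                             tournamentFraction = 0.2) {
  m <- length(rank)
  if (!length(rank) || anyNA(rank) || anyNA(crowding))
    stop("population must be evaluated (rank and crowding populated)")
  tsize <- max(1L, ceiling(tournamentFraction * m))
  winners <- integer(n)
  for (i in seq_len(n)) {
    entrants <- sample.int(m, tsize)
    best <- entrants[rank[entrants] == min(rank[entrants])]
    if (length(best) > 1L)
      best <- best[crowding[best] == max(crowding[best])]
    winners[i] <- if (length(best) > 1L) best[sample.int(length(best), 1L)]
                  else best
  }
  winners
}

## scalar-fitness tournament used by the single-objective baseline
.tournamentSelectScalar <- function(fitness, n = length(fitness),
                                    tournamentFraction = 0.2) {
  m <- length(fitness)
  tsize <- max(1L, ceiling(tournamentFraction * m))
  winners <- integer(n)
  for (i in seq_len(n)) {
    entrants <- sample.int(m, tsize)
    best <- entrants[fitness[entrants] == min(fitness[entrants])]
    winners[i] <- if (length(best) > 1L) best[sample.int(length(best), 1L)]
                  else best
  }
  winners
}

#' One-point crossover of two chromosomes
#'
#' A cut index `i` is drawn uniformly from `0 .. l-1` and the chromosome
#' parts strictly after position `i` (0-based) are exchanged between the
#' parents; `i = l - 1` therefore clones the parents.
#'
#' @param a,b numeric parent chromosomes of equal length.
#' @param cut optional fixed 0-based cut index in `[0, l)`; drawn at random
#'   when `NULL`.
#' @return List of two offspring chromosomes.
#' @examples
#' onePointCrossover(rep(1, 4), rep(2, 4), cut = 1)
#' @export
onePointCrossover <- function(a, b, cut = NULL) {
  l <- length(a)
  if (length(b) != l) stop("parent chromosomes must have equal length")
  if (is.null(cut)) cut <- sample.int(l, 1L) - 1L
  if (cut < 0L || cut >= l) stop("'cut' must lie in [0, l)")
  if (cut < l - 1L) {
    tail <- (cut + 2L):l
    child1 <- c(a[seq_len(cut + 1L)], b[tail])
    child2 <- c(b[seq_len(cut + 1L)], a[tail])
  } else {
    child1 <- a; child2 <- b
  }
  list(child1, child2)
}

#' Bounded polynomial mutation
#'
#' Deb's bounded polynomial mutation: with probability
#' `individualMutationRate` the chromosome is eligible; each gene then
#' mutates independently with probability `geneMutationProb`, drawing a
#' perturbation from the polynomial distribution with index `eta` and
#' staying inside the per-gene bounds. Small `eta` values allow offspring
#' far from the parent.
#'
#' @param genes numeric chromosome.
#' @param lower,upper numeric per-gene bounds (recycled if length 1).
#' @param eta distribution index (> 0; default 0.3).
#' @param geneMutationProb per-gene mutation probability (default 0.07).
#' @param individualMutationRate probability that the chromosome mutates at
#'   all (default 1).
#' @return Mutated chromosome, all genes within bounds.
#' @export
polynomialMutation <- function(genes, lower, upper, eta = 0.3,
                               geneMutationProb = 0.07,
                               individualMutationRate = 1.0) {
  l <- length(genes)
  lower <- rep_len(as.numeric(lower), l)
  upper <- rep_len(as.numeric(upper), l)
  if (any(lower >= upper)) stop("each gene needs lower < upper bounds")
  if (stats::runif(1L) >= individualMutationRate) return(genes)
  hit <- which(stats::runif(l) < geneMutationProb)
  if (!length(hit)) return(genes)
  x <- genes[hit]; lo <- lower[hit]; hi <- upper[hit]
  span <- hi - lo
  u <- stats::runif(length(hit))
  mpow <- 1 / (eta + 1)
  deltaq <- numeric(length(hit))
  low <- u < 0.5
  if (any(low)) {
    xy <- 1 - (x[low] - lo[low]) / span[low]
    val <- 2 * u[low] + (1 - 2 * u[low]) * xy^(eta + 1)
    deltaq[low] <- val^mpow - 1
  }
  if (any(!low)) {
    xy <- 1 - (hi[!low] - x[!low]) / span[!low]
    val <- 2 * (1 - u[!low]) + 2 * (u[!low] - 0.5) * xy^(eta + 1)
    deltaq[!low] <- 1 - val^mpow
  }
  genes[hit] <- pmin(pmax(x + deltaq * span, lo), hi)
  genes
}

#' Environmental selection by rank and crowding
#'
#' NSGA-II (mu + lambda) survivor selection: fronts are admitted in rank
#' order until the target size would be exceeded; the overflowing front is
#' truncated by descending crowding distance (ties broken by original
#' index for determinism).
#'
#' @param objectives numeric matrix `(f1, f2)` of the merged
#'   parent-plus-offspring pool.
#' @param targetSize number of survivors to keep.
#' @return Integer vector of `targetSize` selected row indices.
#' @export
environmentalSelection <- function(objectives, targetSize) {
  objectives <- as.matrix(objectives)
  if (targetSize > nrow(objectives))
    stop("'targetSize' exceeds the pool size")
  fronts <- fastNonDominatedSort(objectives)
  selected <- integer(0)
  for (front in fronts) {
    if (length(selected) + length(front) <= targetSize) {
      selected <- c(selected, front)
      if (length(selected) == targetSize) break
    } else {
      cd <- crowdingDistance(objectives[front, , drop = FALSE])
      ord <- order(-cd, seq_along(front))
      need <- targetSize - length(selected)
      selected <- c(selected, front[ord[seq_len(need)]])
      break
    }
  }
  selected
}

## rank (1-based front number) and within-front crowding for a population
.rankAndCrowd <- function(objectives) {
  fronts <- fastNonDominatedSort(objectives)
  m <- nrow(objectives)
  rank <- integer(m); crowd <- numeric(m)
  for (f in seq_along(fronts)) {
    idx <- fronts[[f]]
    rank[idx] <- f
    crowd[idx] <- crowdingDistance(objectives[idx, , drop = FALSE])
  }
  list(rank = rank, crowd = crowd, fronts = fronts)
}

## evaluate a population matrix; returns m x 2 objective matrix.
## Fitness evaluation consumes no randomness, so parallel evaluation is
## bit-identical to serial.
.evaluatePopulation <- function(coords, pop, k, workers = 1L) {
  rows <- seq_len(nrow(pop))
  evalOne <- function(i) {
    e <- .evalChromosome(coords, pop[i, ], k)
    c(e$f1, e$f2)
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(rows, evalOne, mc.cores = workers)
  } else {
    lapply(rows, evalOne)
  }
  out <- do.call(rbind, res)
  colnames(out) <- c("f1", "f2")
  out
}

## produce the offspring population from selected parents: consecutive
## pairing, one-point crossover with probability cx, then bounded
## polynomial mutation. Consumes RNG in a fixed order.
.variation <- function(parents, config, lower, upper) {
  n <- nrow(parents)
  offspring <- parents
  for (p in seq(1L, n, by = 2L)) {
    if (stats::runif(1L) < config@crossoverProb) {
      ch <- onePointCrossover(parents[p, ], parents[p + 1L, ])
      offspring[p, ] <- ch[[1L]]
      offspring[p + 1L, ] <- ch[[2L]]
    }
  }
  for (i in seq_len(n)) {
    offspring[i, ] <- polynomialMutation(
      offspring[i, ], lower, upper,
      eta = config@mutationEta,
      geneMutationProb = config@geneMutationProb,
      individualMutationRate = config@individualMutationRate)
  }
  offspring
}

#' Select the final solution from a Pareto front
#'
#' Computes the Davies-Bouldin index of the clustering induced by every
#' front member and returns the member minimizing it; ties are broken by
#' the lower compactness objective `f2`, and if every member has an
#' infinite index (fewer than two populated clusters) the minimum-`f2`
#' member is returned.
#'
#' @param front a [ParetoFront-class].
#' @param data the [EmbeddedDataset-class] the front was evolved on.
#' @return List with elements `index` (row in the front), `chromosome`,
#'   `assignment` (a [ClusterAssignment-class]) and `dbi`.
#' @export
selectFinalSolution <- function(front, data) {
  m <- nrow(front@genes)
  if (m < 1L) stop("empty Pareto front")
  dbis <- numeric(m)
  assigns <- vector("list", m)
  for (i in seq_len(m)) {
    protos <- decodeChromosome(front@genes[i, ], front@k, front@d)
    assigns[[i]] <- assignClusters(data, protos)
    dbis[i] <- daviesBouldin(data, protos, assigns[[i]])
  }
  f2 <- front@objectives[, 2L]
  idx <- if (all(is.infinite(dbis))) {
    which.min(f2)
  } else {
    cand <- which(dbis == min(dbis))
    if (length(cand) > 1L) cand <- cand[which.min(f2[cand])]
    cand
  }
  list(index = idx, chromosome = front@genes[idx, ],
       assignment = assigns[[idx]], dbi = dbis[idx])
}

#' Multi-objective evolutionary clustering
#'
#' Evolves a population of prototype chromosomes under the two clustering
#' objectives (separation maximized, compactness minimized): tournament
#' selection by non-domination rank and crowding, one-point crossover,
#' bounded polynomial mutation, and (mu + lambda) survivor selection by
#' non-dominated sorting with crowding truncation. After the final
#' generation the rank-0 front is extracted and the final solution is the
#' front member with minimum Davies-Bouldin index.
#'
#' The run owns one seeded RNG stream; fitness evaluation consumes no
#' randomness, so `workers > 1` changes wall time only and results are
#' identical to a serial run with the same seed.
#'
#' @param data an [EmbeddedDataset-class].
#' @param config a [GAConfig-class].
#' @param verbose print a per-generation log line (generation, best f1,
#'   best f2, front size).
#' @return A [MOGAResult-class].
#' @examples
#' sim <- simulateEmbedded(60, centers = rbind(c(0, 0), c(10, 10)),
#'                         sigma = 0.3, seed = 1)
#' res <- runMOGA(sim$data, gaConfig(k = 2, populationSize = 20,
#'                                   generations = 10, seed = 1))
#' table(clusterLabels(res), sim$truth)
#' @seealso [runSOGA()], [selectFinalSolution()]
#' @export
runMOGA <- function(data, config, verbose = FALSE) {
  validObject(config)
  x <- coords(data)
  d <- ncol(x); k <- config@k
  b <- dimBounds(data)
  lower <- rep(b[, 1L], times = k)
  upper <- rep(b[, 2L], times = k)
  set.seed(config@seed)

  pop <- initializePopulation(data, config)
  objs <- .evaluatePopulation(x, pop, k, config@workers)
  rc <- .rankAndCrowd(objs)
  n <- config@populationSize
  history <- data.frame(generation = integer(0), bestF1 = numeric(0),
                        bestF2 = numeric(0), frontSize = integer(0))
  for (gen in seq_len(config@generations)) {
    parents <- pop[tournamentSelect(rc$rank, rc$crowd, n,
                                    config@tournamentFraction), ,
                   drop = FALSE]
    offspring <- .variation(parents, config, lower, upper)
    offObjs <- .evaluatePopulation(x, offspring, k, config@workers)
    poolPop <- rbind(pop, offspring)
    poolObjs <- rbind(objs, offObjs)
    sel <- environmentalSelection(poolObjs, n)
    pop <- poolPop[sel, , drop = FALSE]
    objs <- poolObjs[sel, , drop = FALSE]
    rc <- .rankAndCrowd(objs)
    history[gen, ] <- list(gen, max(objs[, 1L]), min(objs[, 2L]),
                           length(rc$fronts[[1L]]))
    if (verbose)
      message(sprintf("gen %d: best f1 %.4g, best f2 %.4g, front %d",
                      gen, max(objs[, 1L]), min(objs[, 2L]),
                      length(rc$fronts[[1L]])))
  }
  f0 <- rc$fronts[[1L]]
  front <- new("ParetoFront", genes = pop[f0, , drop = FALSE],
               objectives = objs[f0, , drop = FALSE],
               k = as.integer(k), d = as.integer(d))
  final <- selectFinalSolution(front, data)
  sil <- tryCatch(silhouetteWidth(data, final$assignment),
                  error = function(e) NA_real_)
  report <- new("ValidityReport", sil = sil, nmi = NA_real_,
                ari = NA_real_, dbi = final$dbi)
  new("MOGAResult", front = front, chromosome = final$chromosome,
      assignment = final$assignment, report = report,
      history = history, config = config)
}

#' Single-objective baseline clustering GA
#'
#' Identical encoding, operators and hyperparameters as [runMOGA()], but
#' the scalar fitness is the compactness objective `f2` alone (minimized):
#' plain best-fitness tournaments, no non-dominated sorting and no
#' Davies-Bouldin selection. Survivors are the best `populationSize`
#' chromosomes of the merged parent and offspring pool, so the best `f2`
#' is monotonically non-increasing across generations; the returned
#' solution is the fittest chromosome of the final generation.
#'
#' @inheritParams runMOGA
#' @return A [SOGAResult-class].
#' @export
runSOGA <- function(data, config, verbose = FALSE) {
  validObject(config)
  x <- coords(data)
  d <- ncol(x); k <- config@k
  b <- dimBounds(data)
  lower <- rep(b[, 1L], times = k)
  upper <- rep(b[, 2L], times = k)
  set.seed(config@seed)

  pop <- initializePopulation(data, config)
  f2 <- .evaluatePopulation(x, pop, k, config@workers)[, 2L]
  n <- config@populationSize
  history <- data.frame(generation = integer(0), bestF2 = numeric(0))
  for (gen in seq_len(config@generations)) {
    parents <- pop[.tournamentSelectScalar(f2, n,
                                           config@tournamentFraction), ,
                   drop = FALSE]
    offspring <- .variation(parents, config, lower, upper)
    offF2 <- .evaluatePopulation(x, offspring, k, config@workers)[, 2L]
    poolPop <- rbind(pop, offspring)
    poolF2 <- c(f2, offF2)
    keep <- order(poolF2)[seq_len(n)]
    pop <- poolPop[keep, , drop = FALSE]
    f2 <- poolF2[keep]
    history[gen, ] <- list(gen, min(f2))
    if (verbose)
      message(sprintf("gen %d: best f2 %.4g", gen, min(f2)))
  }
  best <- which.min(f2)
  chrom <- pop[best, ]
  assignment <- assignClusters(data, decodeChromosome(chrom, k, d))
  new("SOGAResult", chromosome = chrom, assignment = assignment,
      f2 = f2[best], history = history, config = config)
}
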