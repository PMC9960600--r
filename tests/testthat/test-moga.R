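test_that("dominance follows the no-worse-and-strictly-better rule", {
  expect_true(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_false(dominates(c(2, 2), c(1, 1)))  # trade-off: incomparable
  expect_true(dominates(c(2, 1), c(2, 2)))   # equal f1, better f2
  expect_false(dominates(c(1, 2), c(2, 1)))
})

test_that("fast non-dominated sort agrees with brute-force peeling", {
  expect_equal(fastNonDominatedSort(matrix(c(3, 1), 1)), list(1L))

  # (2,1) and (1,0.5) trade off f1 against f2; (1,1) is dominated by both
  objs <- rbind(c(2, 1), c(1, 0.5), c(1, 1))
  fronts <- fastNonDominatedSort(objs)
  expect_equal(fronts[[1]], c(1L, 2L))
  expect_equal(fronts[[2]], 3L)

  for (seed in 1:20) {
    objs <- randomObjectives(50, seed)
    got <- fastNonDominatedSort(objs)
    want <- oracleNDS(objs)
    expect_equal(lapply(got, sort), lapply(want, sort))
    expect_equal(sort(unlist(got)), seq_len(nrow(objs)))  # partition
  }
})

test_that("front-1 members are mutually non-dominated", {
  for (seed in 21:25) {
    objs <- randomObjectives(60, seed)
    f0 <- fastNonDominatedSort(objs)[[1]]
    for (i in f0) for (j in f0)
      if (i != j) expect_false(dominates(objs[i, ], objs[j, ]))
  }
})

test_that("crowding distance matches an independent transcription", {
  expect_equal(crowdingDistance(matrix(c(1, 2), 1)), Inf)
  expect_equal(crowdingDistance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))

  # three evenly spaced collinear solutions: ends infinite, middle finite
  cd <- crowdingDistance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_identical(cd[c(1, 3)], c(Inf, Inf))
  expect_equal(cd[2], 2)  # normalized gap of 1 per objective

  for (seed in 1:20) {
    objs <- randomObjectives(30, seed)
    expect_equal(crowdingDistance(objs), oracleCrowding(objs))
  }

  # zero objective range contributes nothing
  flat <- cbind(rep(1, 4), c(1, 2, 3, 4))
  expect_equal(crowdingDistance(flat)[2:3],
               oracleCrowding(flat)[2:3])
})

test_that("tournament selection favors rank then crowding", {
  # a unique rank-1 chromosome wins every full tournament
  rank <- c(1L, rep(2L, 9L))
  crowd <- rep(0, 10)
  set.seed(1)
  expect_true(all(tournamentSelect(rank, crowd, n = 50,
                                   tournamentFraction = 1) == 1L))

  # with distinct ranks, the best chromosome wins exactly when sampled:
  # empirical win rate ~ tournament inclusion probability
  rank <- 1:10
  set.seed(2)
  wins <- tournamentSelect(rank, rep(0, 10), n = 10000,
                           tournamentFraction = 0.2)
  expect_equal(mean(wins == 1L), 2 / 10, tolerance = 0.02 / 0.2)

  # within equal rank, larger crowding wins
  set.seed(3)
  sel <- tournamentSelect(c(1L, 1L), c(0, 5), n = 200,
                          tournamentFraction = 1)
  expect_true(all(sel == 2L))

  expect_error(tournamentSelect(c(NA_integer_, 1L), c(1, 1)), "evaluated")
})

test_that("one-point crossover exchanges suffixes and conserves genes", {
  got <- onePointCrossover(rep(1, 4), rep(2, 4), cut = 1)
  expect_equal(got[[1]], c(1, 1, 2, 2))
  expect_equal(got[[2]], c(2, 2, 1, 1))

  a <- c(9, 8, 7)
  for (cut in 0:2)
    expect_equal(onePointCrossover(a, a, cut = cut), list(a, a))
  # cut = l - 1 clones the parents
  expect_equal(onePointCrossover(1:3, 4:6, cut = 2), list(1:3, 4:6))
  expect_error(onePointCrossover(1:3, 1:4), "equal length")

  set.seed(4)
  for (trial in 1:200) {
    a <- runif(6); b <- runif(6)
    ch <- onePointCrossover(a, b)
    for (pos in 1:6)
      expect_setequal(c(ch[[1]][pos], ch[[2]][pos]), c(a[pos], b[pos]))
  }
})

test_that("polynomial mutation respects bounds and rates", {
  g <- c(0.5, 0.2, 0.9)
  set.seed(5)
  expect_equal(polynomialMutation(g, 0, 1, geneMutationProb = 0), g)
  expect_error(polynomialMutation(g, 1, 0), "lower < upper")

  set.seed(6)
  out <- replicate(10000,
    polynomialMutation(0.5, lower = -2, upper = 3, geneMutationProb = 1))
  expect_true(all(out >= -2 & out <= 3))
  expect_gt(sd(out), 0)

  # realized change rate ~ individualMutationRate * geneMutationProb
  set.seed(7)
  l <- 500
  changed <- replicate(200, {
    m <- polynomialMutation(rep(0.5, l), 0, 1, geneMutationProb = 0.07,
                            individualMutationRate = 0.8)
    mean(m != 0.5)
  })
  expect_equal(mean(changed), 0.8 * 0.07, tolerance = 0.01 / (0.8 * 0.07))
})

test_that("environmental selection keeps whole fronts then truncates by crowding", {
  # unique non-dominated pool (f1 and f2 rise together: pure trade-off)
  # of exactly the target size: identity
  objs <- cbind(1:5, 1:5)
  expect_setequal(environmentalSelection(objs, 5), 1:5)

  # rank-0 front overflowing by 2: boundaries kept, most crowded interior kept
  objs <- cbind(c(0, 1, 1.1, 2, 3), c(0, 1, 1.1, 2, 3))
  sel <- environmentalSelection(objs, 3)
  expect_true(all(c(1, 5) %in% sel))  # infinite boundary crowding

  expect_error(environmentalSelection(objs, 9), "pool")

  # never discards a rank-0 solution while keeping a dominated one
  for (seed in 31:40) {
    objs <- randomObjectives(40, seed)
    sel <- environmentalSelection(objs, 15)
    expect_length(sel, 15)
    fronts <- oracleNDS(objs)
    rank <- integer(nrow(objs))
    for (f in seq_along(fronts)) rank[fronts[[f]]] <- f
    worstKept <- max(rank[sel])
    if (worstKept > 1)
      expect_true(all(rank[setdiff(seq_len(nrow(objs)), sel)] >=
                        worstKept))
    # matches a slow reference: fronts below the cut fully included
    for (f in seq_along(fronts)) {
      inside <- sum(fronts[[f]] %in% sel)
      expect_true(inside == length(fronts[[f]]) || inside == 0 ||
                    f == worstKept)
    }
  }
})

test_that("rank-0 hypervolume is non-decreasing while the front fits", {
  # (mu+lambda) elitism preserves hypervolume as long as the rank-0 front
  # fits within the survivor budget; once it overflows, crowding
  # truncation may drop interior members, but the objective-space corners
  # (best f1, best f2) remain monotone throughout.
  set.seed(8)
  ref <- c(-1, 31)
  pool <- randomObjectives(30, 99)
  current <- pool[environmentalSelection(pool, 10), ]
  hv <- hypervolume2d(current, ref)
  bestF1 <- max(current[, 1]); bestF2 <- min(current[, 2])
  for (step in 1:15) {
    offspring <- randomObjectives(10, 200 + step)
    merged <- rbind(current, offspring)
    frontFits <- length(oracleNDS(merged)[[1]]) <= 10
    current <- merged[environmentalSelection(merged, 10), ]
    hvNew <- hypervolume2d(current, ref)
    if (frontFits) expect_gte(hvNew, hv - 1e-12)
    expect_gte(max(current[, 1]), bestF1)
    expect_lte(min(current[, 2]), bestF2)
    hv <- hvNew
    bestF1 <- max(current[, 1]); bestF2 <- min(current[, 2])
  }
})

test_that("MOGA recovers well-separated blobs and selects by DBI", {
  sim <- simulateEmbedded(100, rbind(c(0, 0), c(10, 0)), sigma = 0.1,
                          seed = 9)
  res <- runMOGA(sim$data, gaConfig(k = 2, populationSize = 50,
                                    generations = 30, seed = 10))
  expect_equal(ari(clusterLabels(res), sim$truth), 1)
  protos <- prototypes(res)
  truthCenters <- rbind(c(0, 0), c(10, 0))
  # match prototypes to nearest true centers
  err <- apply(protos, 1, function(p)
    min(sqrt(colSums((t(truthCenters) - p)^2))))
  expect_true(all(err < 0.5))
  expect_lt(res@report@dbi, 0.2)
})

test_that("k = 1 degenerates to the compactness-only solution", {
  sim <- simulateEmbedded(60, matrix(c(0, 0), 1), sigma = 1, seed = 12)
  res <- runMOGA(sim$data, gaConfig(k = 1, populationSize = 30,
                                    generations = 20, seed = 12))
  expect_true(all(objectivePairs(paretoFront(res))[, "f1"] == 0))
  expect_identical(res@report@dbi, Inf)
  # fallback: minimum f2 member selected; prototype near the data center
  expect_lt(sqrt(sum((res@chromosome - colMeans(coords(sim$data)))^2)), 1)
})

test_that("MOGA runs are reproducible and worker-count independent", {
  sim <- blobData(k = 3, nCells = 60, seed = 13)
  cfg <- gaConfig(k = 3, populationSize = 30, generations = 10, seed = 14)
  r1 <- runMOGA(sim$data, cfg)
  r2 <- runMOGA(sim$data, cfg)
  expect_identical(r1@front@genes, r2@front@genes)
  expect_identical(clusterLabels(r1), clusterLabels(r2))

  cfg4 <- cfg; cfg4@workers <- 4L
  r4 <- runMOGA(sim$data, cfg4)
  expect_identical(r1@front@genes, r4@front@genes)
  expect_identical(clusterLabels(r1), clusterLabels(r4))
  expect_identical(r1@front@objectives, r4@front@objectives)
})

test_that("final-solution selection minimizes DBI with f2 tie-break", {
  sim <- blobData(k = 2, nCells = 40, seed = 15)
  res <- runMOGA(sim$data, gaConfig(k = 2, populationSize = 30,
                                    generations = 15, seed = 16))
  fr <- paretoFront(res)
  final <- selectFinalSolution(fr, sim$data)
  # explicit enumeration oracle
  dbis <- vapply(seq_len(nrow(fr@genes)), function(i) {
    p <- decodeChromosome(fr@genes[i, ], fr@k, fr@d)
    daviesBouldin(sim$data, p, assignClusters(sim$data, p))
  }, numeric(1))
  expect_equal(final$dbi, min(dbis))
  expect_equal(final$chromosome, res@chromosome)
})

test_that("SOGA is elitist, reproducible, and recovers blobs", {
  sim <- simulateEmbedded(80, rbind(c(0, 0), c(10, 10)), sigma = 0.2,
                          seed = 17)
  cfg <- gaConfig(k = 2, populationSize = 40, generations = 25, seed = 18)
  r1 <- runSOGA(sim$data, cfg)
  expect_equal(ari(clusterLabels(r1), sim$truth), 1)
  expect_true(all(diff(r1@history$bestF2) <= 1e-12))
  r2 <- runSOGA(sim$data, cfg)
  expect_identical(r1@chromosome, r2@chromosome)
  expect_identical(clusterLabels(r1), clusterLabels(r2))
})

test_that("population initialization respects and spans dimension bounds", {
  ed <- EmbeddedDataset(rbind(c(0, 2), c(5, 7)))  # bounds [0,5] x [2,7]
  cfg <- gaConfig(k = 2, populationSize = 100, generations = 1)
  set.seed(19)
  pop <- initializePopulation(ed, cfg)
  expect_equal(dim(pop), c(100, 4))
  d1 <- pop[, c(1, 3)]; d2 <- pop[, c(2, 4)]
  expect_true(all(d1 >= 0 & d1 <= 5) && all(d2 >= 2 & d2 <= 7))
  # spans at least 95% of each range with many samples
  set.seed(20)
  cfg2 <- gaConfig(k = 1, populationSize = 5000, generations = 1)
  pop2 <- initializePopulation(ed, cfg2)
  expect_lt(min(pop2[, 1]), 0 + 0.05 * 5)
  expect_gt(max(pop2[, 1]), 5 - 0.05 * 5)
  set.seed(21); a <- initializePopulation(ed, cfg)
  set.seed(21); b <- initializePopulation(ed, cfg)
  expect_identical(a, b)
})
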