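test_that("chromosome decoding slices prototypes in order", {
  expect_equal(decodeChromosome(c(0, 0, 2, 0), k = 2, d = 2),
               rbind(c(0, 0), c(2, 0)))
  expect_equal(decodeChromosome(c(5.5, -1.0), k = 1, d = 2),
               matrix(c(5.5, -1.0), nrow = 1))
  expect_error(decodeChromosome(1:5, k = 2, d = 2), "length")
  # round trip
  set.seed(3)
  p <- matrix(rnorm(12), nrow = 4)
  expect_equal(decodeChromosome(encodePrototypes(p), 4, 3), p)
})

test_that("nearest-prototype assignment matches the exhaustive oracle", {
  ed <- EmbeddedDataset(rbind(c(0, 0), c(1, 0)))
  protos <- rbind(c(0, 0), c(9, 9))
  expect_equal(clusterLabels(assignClusters(ed, protos))[1], 1L)
  # equidistant tie goes to the lowest prototype index
  tie <- assignClusters(EmbeddedDataset(matrix(c(1, 0), 1)),
                        rbind(c(0, 0), c(2, 0)))
  expect_equal(clusterLabels(tie), 1L)
  expect_error(assignClusters(ed, matrix(1, 1, 3)), "dimension")

  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(runif(100, -5, 5), ncol = 2)
    protos <- matrix(runif(8, -5, 5), ncol = 2)
    got <- clusterLabels(assignClusters(EmbeddedDataset(x), protos))
    expect_equal(got, oracleAssign(x, protos))
  }
})

test_that("separation objective follows the weighted prototype-spread formula", {
  ed1 <- EmbeddedDataset(matrix(rnorm(10), ncol = 2))
  protos1 <- matrix(c(3, 4), 1)
  a1 <- assignClusters(ed1, protos1)
  expect_equal(objectiveSeparation(protos1, a1), 0)  # k = 1: z_bar = z_1

  # two prototypes at (0,0) and (2,0), one cell each: 1*1 + 1*1
  protos <- rbind(c(0, 0), c(2, 0))
  a <- ClusterAssignment(c(1L, 2L), k = 2)
  expect_equal(objectiveSeparation(protos, a), 2)

  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(runif(60, -3, 3), ncol = 2)
    protos <- matrix(runif(10, -3, 3), ncol = 2)
    a <- assignClusters(EmbeddedDataset(x), protos)
    expect_equal(objectiveSeparation(protos, a),
                 oracleF1(protos, clusterLabels(a)), tolerance = 1e-9)
  }
})

test_that("compactness objective follows the within-cluster distance sum", {
  # cells on their prototypes
  x <- rbind(c(0, 0), c(5, 5))
  ed <- EmbeddedDataset(x)
  a <- assignClusters(ed, x)
  expect_equal(objectiveCompactness(ed, x, a), 0)

  ed2 <- EmbeddedDataset(rbind(c(0, 0), c(0, 2)))
  protos2 <- matrix(c(0, 1), 1)
  expect_equal(objectiveCompactness(ed2, protos2,
                                    ClusterAssignment(c(1L, 1L), 1)), 2)

  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(runif(60, -3, 3), ncol = 2)
    protos <- matrix(runif(10, -3, 3), ncol = 2)
    ed <- EmbeddedDataset(x)
    a <- assignClusters(ed, protos)
    expect_equal(objectiveCompactness(ed, protos, a),
                 oracleF2(x, protos, clusterLabels(a)), tolerance = 1e-9)
  }
})

test_that("objectives are non-negative and f2 is isometry-invariant", {
  set.seed(11)
  x <- matrix(runif(80, -4, 4), ncol = 2)
  protos <- matrix(runif(12, -4, 4), ncol = 2)
  ed <- EmbeddedDataset(x)
  a <- assignClusters(ed, protos)
  f1 <- objectiveSeparation(protos, a)
  f2 <- objectiveCompactness(ed, protos, a)
  expect_gte(f1, 0)
  expect_gte(f2, 0)
  # joint rotation + translation leaves f2 unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  shift <- c(3, -2)
  xr <- sweep(x %*% R, 2, shift, "+")
  pr <- sweep(protos %*% R, 2, shift, "+")
  ar <- assignClusters(EmbeddedDataset(xr), pr)
  expect_equal(clusterLabels(ar), clusterLabels(a))
  expect_equal(objectiveCompactness(EmbeddedDataset(xr), pr, ar), f2,
               tolerance = 1e-9)
})

test_that("Davies-Bouldin index matches a literal transcription", {
  # two singleton clusters: zero scatter
  ed <- EmbeddedDataset(rbind(c(0, 0), c(4, 0)))
  protos <- rbind(c(0, 0), c(4, 0))
  a <- assignClusters(ed, protos)
  expect_equal(daviesBouldin(ed, protos, a), 0)

  # two clusters of two cells at +-1 around prototypes 10 apart:
  # S_i = 1 each, ratio 2/10
  x <- rbind(c(-1, 0), c(1, 0), c(9, 0), c(11, 0))
  protos <- rbind(c(0, 0), c(10, 0))
  ed <- EmbeddedDataset(x)
  a <- assignClusters(ed, protos)
  expect_equal(daviesBouldin(ed, protos, a), 0.2)

  # fewer than two populated clusters: infinite sentinel
  far <- rbind(c(0, 0), c(50, 50))
  aa <- assignClusters(ed, far)
  expect_true(all(clusterLabels(aa) == 1L))
  expect_identical(daviesBouldin(ed, far, aa), Inf)

  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(runif(80, -5, 5), ncol = 2)
    protos <- matrix(runif(10, -5, 5), ncol = 2)
    ed <- EmbeddedDataset(x)
    a <- assignClusters(ed, protos)
    expect_equal(daviesBouldin(ed, protos, a),
                 oracleDBI(x, protos, clusterLabels(a)), tolerance = 1e-9)
  }
})

test_that("assignment and embedding validity contracts hold", {
  expect_error(EmbeddedDataset(matrix(c(1, NA), 1)), "finite")
  expect_error(ClusterAssignment(c(1L, 5L), k = 2), "1..k")
  ca <- ClusterAssignment(c(1L, 1L, 3L), k = 3)
  expect_equal(clusterSizes(ca), c(2L, 0L, 1L))  # empty cluster allowed
  expect_equal(sum(clusterSizes(ca)), 3L)
})
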