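library(SingleCellExperiment)

test_that("filtering applies the four steps in order on a toy matrix", {
  # 6 genes x 5 cells; gene_006 expressed in 2 cells (< 3) -> dropped;
  # cell_005 then expresses only 2 genes (< 3) -> dropped
  m <- rbind(
    gene_001 = c(5, 6, 4, 5, 9),
    gene_002 = c(3, 2, 2, 4, 0),
    gene_003 = c(4, 4, 6, 3, 2),
    gene_004 = c(2, 3, 5, 2, 0),
    gene_005 = c(6, 5, 3, 6, 0),
    gene_006 = c(1, 2, 0, 0, 0))
  colnames(m) <- paste0("cell_", 1:5)
  cfg <- preprocessConfig(minGenesPerCell = 3, minCellsPerGene = 3,
                          reducer = "pca")
  out <- filterCellsAndGenes(m, cfg)
  expect_equal(rownames(out), paste0("gene_00", 1:5))
  expect_equal(colnames(out), paste0("cell_", 1:4))
  log <- S4Vectors::metadata(out)$filterLog$steps
  expect_equal(log$removedGenes[log$step == "gene_min_cells"], 1L)
  expect_equal(log$removedCells[log$step == "cell_min_genes"], 1L)
})

test_that("mitochondrial filter removes high-mito cells and is vacuous without MT genes", {
  sce <- tinyCounts(nGenes = 20, nCells = 10, seed = 50, mitoGenes = 2)
  m <- assay(sce, "counts")
  m[1:2, ] <- 1L    # keep baseline mito fraction ~2%
  m[1:2, 1] <- 500  # cell 1: mito fraction >> 10%
  cfg <- preprocessConfig(minGenesPerCell = 1, minCellsPerGene = 1,
                          outlierSD = 50, reducer = "pca")
  out <- filterCellsAndGenes(SingleCellExperiment(list(counts = m)), cfg)
  expect_false("cell_001" %in% colnames(out))
  expect_equal(ncol(out), 9)

  noMito <- tinyCounts(nGenes = 20, nCells = 10, seed = 50)
  out2 <- filterCellsAndGenes(noMito, cfg)
  log <- S4Vectors::metadata(out2)$filterLog$steps
  expect_equal(log$removedCells[log$step == "cell_mito_fraction"], 0L)
})

test_that("outlier bounds degenerate gracefully and trim extreme cells", {
  # all cells identical: zero sd, nothing removed
  m <- matrix(5L, nrow = 10, ncol = 6,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  cfg <- preprocessConfig(minGenesPerCell = 1, minCellsPerGene = 1,
                          reducer = "pca")
  out <- filterCellsAndGenes(m, cfg)
  expect_equal(ncol(out), 6)

  # one cell with a wildly larger library is trimmed
  set.seed(51)
  m2 <- matrix(rpois(20 * 30, 5), nrow = 20,
               dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
  m2[, 1] <- m2[, 1] * 1000
  out2 <- filterCellsAndGenes(m2, cfg)
  expect_false("c1" %in% colnames(out2))
})

test_that("structural filter steps are idempotent", {
  sce <- tinyCounts(nGenes = 50, nCells = 30, seed = 52)
  cfg <- preprocessConfig(minGenesPerCell = 5, minCellsPerGene = 3,
                          outlierSD = 50, reducer = "pca")
  once <- filterCellsAndGenes(sce, cfg)
  twice <- filterCellsAndGenes(once, cfg)
  expect_equal(dim(twice), dim(once))
  expect_equal(as.matrix(assay(twice)), as.matrix(assay(once)))
})

test_that("HVG selection recovers planted variable genes", {
  set.seed(53)
  g <- 300; n <- 100
  # bulk genes span a range of means so the mean-variance trend is
  # anchored; planted genes sit inside that range but carry a strong
  # between-group signal inflating their variance far above the trend
  lambda <- rlnorm(g, meanlog = 1.5, sdlog = 0.8)
  base <- matrix(rpois(g * n, rep(lambda, n)), nrow = g)
  grp <- rep(1:2, each = n / 2)
  for (i in 1:10) {
    base[i, grp == 1] <- rpois(n / 2, 2)
    base[i, grp == 2] <- rpois(n / 2, 30)
  }
  rownames(base) <- sprintf("g%03d", seq_len(g))
  colnames(base) <- sprintf("c%03d", seq_len(n))
  cfg <- preprocessConfig(nHVG = 50, reducer = "pca")
  out <- selectHVG(base, cfg)
  expect_equal(nrow(out), 50)
  expect_true(all(sprintf("g%03d", 1:10) %in% rownames(out)))
  # subset property: output genes are input genes, original order
  expect_true(all(rownames(out) %in% rownames(base)))
  expect_false(is.unsorted(match(rownames(out), rownames(base))))
})

test_that("zero-variance genes never outrank variable genes and small inputs warn", {
  sce <- tinyCounts(nGenes = 30, nCells = 20, seed = 54)
  m <- assay(sce)
  m[1, ] <- 7L  # constant gene
  cfg <- preprocessConfig(nHVG = 20, reducer = "pca")
  out <- selectHVG(m, cfg)
  expect_false("gene_001" %in% rownames(out))

  expect_warning(selectHVG(m[1:5, ], cfg), "keeping all")
})

test_that("HVG selection is invariant to gene ordering", {
  sce <- tinyCounts(nGenes = 60, nCells = 40, seed = 55)
  m <- assay(sce)
  cfg <- preprocessConfig(nHVG = 25, reducer = "pca")
  a <- rownames(selectHVG(m, cfg))
  set.seed(56)
  perm <- sample(nrow(m))
  b <- rownames(selectHVG(m[perm, ], cfg))
  expect_setequal(a, b)
})

test_that("log-normalization and scaling produce standardized genes", {
  m <- matrix(c(1, 2, 3,
                4, 0, 2,
                5, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  s <- logNormalizeScale(m)
  # constant-after-normalization rows map to zero; others standardized
  lib <- colSums(m); target <- median(lib)
  want <- log1p(sweep(m, 2, lib, "/") * target)
  for (i in 1:3) {
    row <- want[i, ]
    expect_equal(as.numeric(s[i, ]),
                 if (sd(row) > 0) as.numeric((row - mean(row)) / sd(row))
                 else rep(0, 3),
                 tolerance = 1e-9)
  }
  sce <- tinyCounts(nGenes = 40, nCells = 25, seed = 57)
  s2 <- logNormalizeScale(sce)
  expect_true(all(abs(rowMeans(s2)) < 1e-9))
  vars <- apply(s2, 1, var)
  expect_true(all(abs(vars[vars > 0] - 1) < 1e-9))
  expect_error(logNormalizeScale(matrix(-1, 2, 2)), "non-negative")
})

test_that("PCA reduction captures planted low-rank structure", {
  set.seed(58)
  # exact plane in 10-D
  basis <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:2]
  x2 <- matrix(rnorm(200), ncol = 2) %*% t(basis)  # 100 cells x 10 "genes"
  cfg <- preprocessConfig(nPCs = 5, reducer = "pca")
  ed <- reduceDimensions(t(x2), cfg)
  ev <- metadata(ed)$explainedVariance
  expect_gt(sum(ev[1:2]), 1 - 1e-9)

  # 3 strong signal dimensions + tiny noise: 10 PCs explain > 98%
  sig <- matrix(rnorm(100 * 3, sd = 5), ncol = 3) %*%
    t(qr.Q(qr(matrix(rnorm(400), 20)))[, 1:3])
  noisy <- sig + matrix(rnorm(length(sig), sd = 0.05), nrow = nrow(sig))
  noisy <- sweep(noisy, 2, colMeans(noisy))
  ed2 <- reduceDimensions(t(noisy), preprocessConfig(reducer = "pca"))
  expect_gt(sum(metadata(ed2)$explainedVariance), 0.98)

  expect_error(reduceDimensions(matrix(1:4, ncol = 1),
                                preprocessConfig(reducer = "pca")),
               "cells")
})

test_that("the PCA pipeline is equivariant to cell ordering", {
  sce <- simulateCounts(simulationConfig(nCells = 120, nGenes = 300,
                                         nGroups = 3, seed = 59))
  cfg <- preprocessConfig(minGenesPerCell = 10, reducer = "pca")
  ed <- suppressWarnings(preprocessCounts(sce, cfg))
  set.seed(60)
  perm <- sample(ncol(sce))
  edP <- suppressWarnings(preprocessCounts(sce[, perm], cfg))
  common <- intersect(cellIds(ed), cellIds(edP))
  expect_setequal(cellIds(ed), cellIds(edP))
  expect_equal(coords(edP)[common, ], coords(ed)[common, ],
               tolerance = 1e-6)
})
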