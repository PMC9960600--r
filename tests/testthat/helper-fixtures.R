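# Shared fixtures, all generated in code.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
})

# small deterministic count container with optional mito genes
tinyCounts <- function(nGenes = 30, nCells = 20, seed = 42,
                       mitoGenes = 0) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nCells, lambda = 5), nrow = nGenes)
  ids <- sprintf("gene_%03d", seq_len(nGenes))
  if (mitoGenes > 0)
    ids[seq_len(mitoGenes)] <- sprintf("MT-%03d", seq_len(mitoGenes))
  rownames(m) <- ids
  colnames(m) <- sprintf("cell_%03d", seq_len(nCells))
  SingleCellExperiment(assays = list(counts = m))
}

blobData <- function(k = 3, nCells = 90, sep = 10, sigma = 0.3,
                     seed = 1) {
  ang <- 2 * pi * seq_len(k) / k
  centers <- sep * cbind(cos(ang), sin(ang))
  simulateEmbedded(nCells, centers, sigma = sigma, seed = seed)
}

# Memoized full-protocol runs shared by the acceptance checks: one
# simulated dataset per group count, preprocessed with the default
# pipeline, clustered by MOGA with 5 run seeds each.
.acceptCache <- new.env(parent = emptyenv())

acceptanceRuns <- function(ks = c(2, 4, 8, 16), dataSeeds = seq_along(ks),
                           runSeeds = 101:105) {
  key <- paste(c(ks, dataSeeds, runSeeds), collapse = "_")
  if (!is.null(.acceptCache[[key]])) return(.acceptCache[[key]])
  out <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    sce <- simulateCounts(simulationConfig(nCells = 1000, nGenes = 2000,
                                           nGroups = k,
                                           seed = dataSeeds[i]))
    ed <- suppressWarnings(
      preprocessCounts(sce, preprocessConfig(reducer = "umap", seed = 1)))
    truth <- trueLabels(sce, ed)
    runs <- lapply(runSeeds, function(s) {
      res <- runMOGA(ed, gaConfig(k = k, populationSize = 100,
                                  generations = 50, seed = s))
      list(sil = res@report@sil,
           nmi = nmi(clusterLabels(res), truth),
           ari = ari(clusterLabels(res), truth))
    })
    list(k = k,
         sil = vapply(runs, `[[`, numeric(1), "sil"),
         nmi = vapply(runs, `[[`, numeric(1), "nmi"),
         ari = vapply(runs, `[[`, numeric(1), "ari"))
  })
  names(out) <- paste0("k", ks)
  .acceptCache[[key]] <- out
  out
}
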