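#' Derive the cluster count from an automatic cluster estimate
#'
#' Community-detection methods tend to over-partition single-cell data;
#' when a reference number of automatically detected communities `kph` is
#' available, the prototype count is set to `0.3 * kph`, rounded half-up,
#' with a floor of 2.
#'
#' @param kph positive integer, e.g. the number of communities detected by
#'   a graph-based method.
#' @return Integer cluster count.
#' @examples
#' kFromKph(20)  # 6
#' @export
kFromKph <- function(kph) {
  if (kph < 1L) stop("'kph' must be positive")
  max(2L, as.integer(floor(0.3 * kph + 0.5)))
}

#' Run the end-to-end clustering pipeline
#'
#' Orchestrates simulate/load, preprocess, cluster, and evaluate stages,
#' writing every intermediate artifact plus a machine-readable manifest
#' (stage inputs, seeds, wall times, outputs) to `outDir`.
#'
#' The `config` is a nested list (typically read from YAML via
#' [yaml::read_yaml()]) with any of:
#'
#' * `simulate`: arguments for [simulationConfig()]; or `input`: a path to
#'   a 10x MTX directory or a dense CSV/TSV count table;
#' * `preprocess`: arguments for [preprocessConfig()];
#' * `cluster`: `algorithm` (`"moga"` or `"soga"`), `k` (or `kph`), plus
#'   arguments for [gaConfig()];
#' * `evaluate`: `TRUE` to write a validity report (external metrics are
#'   included when simulated truth is available).
#'
#' @param config nested configuration list.
#' @param outDir output directory.
#' @return Invisibly, a list with the artifacts (`embedding`, `result`,
#'   `report`, `manifest`).
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mogaclust",
                   version = as.character(utils::packageVersion("mogaclust")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  stamp <- function(stage, t0, detail) {
    manifest$stages[[stage]] <<- c(
      list(elapsedSeconds = round(as.numeric(proc.time()[3L] - t0), 3)),
      detail)
  }

  counts <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    t0 <- proc.time()[3L]
    simCfg <- do.call(simulationConfig, config$simulate)
    counts <- simulateCounts(simCfg)
    truth <- trueLabels(counts)
    writeCounts10x(counts, file.path(outDir, "counts"))
    stamp("simulate", t0, list(seed = simCfg@seed,
                               nCells = simCfg@nCells,
                               nGroups = simCfg@nGroups,
                               output = "counts/"))
  } else if (!is.null(config$input)) {
    t0 <- proc.time()[3L]
    counts <- if (dir.exists(config$input)) readCounts10x(config$input)
              else readCountsCSV(config$input)
    stamp("load", t0, list(input = config$input))
  }

  embedding <- NULL
  if (!is.null(counts)) {
    t0 <- proc.time()[3L]
    preCfg <- do.call(preprocessConfig,
                      as.list(config$preprocess %||% list()))
    embedding <- preprocessCounts(counts, preCfg)
    writeEmbedding(embedding, file.path(outDir, "coords.csv"))
    stamp("preprocess", t0, list(seed = preCfg@seed,
                                 reducer = preCfg@reducer,
                                 cells = length(cellIds(embedding)),
                                 output = "coords.csv"))
  }

  result <- NULL
  if (!is.null(config$cluster)) {
    if (is.null(embedding)) stop("clustering requires an input stage")
    t0 <- proc.time()[3L]
    cc <- config$cluster
    algorithm <- tolower(cc$algorithm %||% "moga")
    k <- if (!is.null(cc[["k"]])) cc[["k"]] else kFromKph(cc[["kph"]])
    gaArgs <- cc[setdiff(names(cc), c("algorithm", "kph"))]
    gaArgs$k <- k
    cfg <- do.call(gaConfig, gaArgs)
    result <- if (algorithm == "soga") runSOGA(embedding, cfg)
              else runMOGA(embedding, cfg)
    writeLabels(result@assignment, cellIds(embedding),
                file.path(outDir, "labels.csv"))
    writePrototypes(prototypes(result), file.path(outDir,
                                                  "prototypes.csv"))
    if (is(result, "MOGAResult")) {
      fr <- paretoFront(result)
      utils::write.csv(
        data.frame(objectivePairs(fr), fr@genes),
        file.path(outDir, "front.csv"), row.names = FALSE)
    }
    stamp("cluster", t0, list(algorithm = algorithm, k = k,
                              seed = cfg@seed,
                              outputs = c("labels.csv",
                                          "prototypes.csv")))
  }

  report <- NULL
  if (isTRUE(config$evaluate) && !is.null(result)) {
    t0 <- proc.time()[3L]
    tr <- if (!is.null(truth)) trueLabels(counts, embedding) else NULL
    report <- validityReport(embedding, result@assignment, truth = tr,
                             prototypes = prototypes(result))
    jsonlite::write_json(
      list(sil = report@sil, nmi = report@nmi, ari = report@ari,
           dbi = if (is.infinite(report@dbi)) "Inf" else report@dbi),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    stamp("evaluate", t0, list(output = "report.json"))
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(counts = counts, embedding = embedding, result = result,
                 report = report, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
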