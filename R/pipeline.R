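# End-to-end orchestration: inputs (files or synthetic) -> diversity table,
# depth summaries, nestedness table, correlations, clade contributions,
# manifest.

#' Pipeline configuration
#'
#' Collects input paths (or a synthetic configuration) and the analysis
#' settings. The defaults are the canonical ones: a ten-species richness
#' filter, 10-Myr slice interval, 1-degree latitudinal bins, 1000 null
#' replicates and a 13 degrees N restriction threshold.
#'
#' @param treePath,presencePath,gridPath,envPath,cladeMapPath,observedLatPath
#'   input file paths (see the read* functions for formats). Leave NULL and
#'   supply `synthetic` to generate inputs instead.
#' @param synthetic optional [syntheticConfig()]; used when `treePath` is
#'   NULL.
#' @param outDir output directory (created if missing).
#' @param minRichness cells below this species richness are dropped
#'   (default 10).
#' @param binWidth latitudinal bin width in degrees (default 1).
#' @param thresholdLat restriction threshold latitude (default 13).
#' @param sliceInterval evolutionary depth step in Myr (default 10); the
#'   root age itself is always appended.
#' @param maxDepth deepest slice (default: the root age).
#' @param replicates r1 null replicates per depth (default 1000).
#' @param seed master seed for every stochastic step.
#' @param fillEmbedded,adjacentOnly turnover counting flags, see
#'   [turnoverObserved()].
#' @param includeRootPath PD convention, see [faithPD()].
#' @param triVariant ruggedness variant, see [terrainRuggedness()].
#' @param clipObserved clip ranges to observed latitudes before analysis
#'   (requires observed latitudes; default FALSE).
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(treePath = NULL, presencePath = NULL,
                           gridPath = NULL, envPath = NULL,
                           cladeMapPath = NULL, observedLatPath = NULL,
                           synthetic = NULL, outDir = tempfile("phylogradient_"),
                           minRichness = 10, binWidth = 1, thresholdLat = 13,
                           sliceInterval = 10, maxDepth = NULL,
                           replicates = 1000, seed = 1,
                           fillEmbedded = TRUE, adjacentOnly = FALSE,
                           includeRootPath = TRUE,
                           triVariant = "mean", clipObserved = FALSE) {
  if (is.null(treePath) && is.null(synthetic))
    synthetic <- syntheticConfig(seed = seed)
  cfg <- list(treePath = treePath, presencePath = presencePath,
              gridPath = gridPath, envPath = envPath,
              cladeMapPath = cladeMapPath, observedLatPath = observedLatPath,
              synthetic = synthetic, outDir = outDir,
              minRichness = minRichness, binWidth = binWidth,
              thresholdLat = thresholdLat, sliceInterval = sliceInterval,
              maxDepth = maxDepth, replicates = replicates, seed = seed,
              fillEmbedded = fillEmbedded, adjacentOnly = adjacentOnly,
              includeRootPath = includeRootPath, triVariant = triVariant,
              clipObserved = clipObserved)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; a `synthetic` mapping is
#' passed to [syntheticConfig()].
#'
#' @param path YAML file.
#' @return list of class `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    if (!is.null(y$synthetic$latRange)) y$synthetic$latRange <- as.numeric(y$synthetic$latRange)
    if (!is.null(y$synthetic$cwdRange)) y$synthetic$cwdRange <- as.numeric(y$synthetic$cwdRange)
    if (!is.null(y$synthetic$mapRange)) y$synthetic$mapRange <- as.numeric(y$synthetic$mapRange)
    if (!is.null(y$synthetic$envNoiseSd)) y$synthetic$envNoiseSd <- unlist(y$synthetic$envNoiseSd)
    y$synthetic <- do.call(syntheticConfig, y$synthetic)
  }
  do.call(pipelineConfig, y)
}

# load (or simulate) all inputs for a pipeline run
.loadInputs <- function(config) {
  if (is.null(config$treePath)) {
    sim <- simulateCommunity(config$synthetic)
    return(list(tree = sim$tree, grid = sim$grid, env = sim$landscape$env,
                cladeMap = sim$cladeMap, observedLat = sim$observedLat,
                synthetic = TRUE))
  }
  for (p in c(config$treePath, config$presencePath, config$gridPath))
    if (is.null(p) || !file.exists(p))
      stop("input file missing: ", if (is.null(p)) "(unset path)" else p)
  list(tree = readTimeTree(config$treePath),
       grid = readPresenceGrid(config$presencePath, config$gridPath),
       env = if (!is.null(config$envPath)) readEnvTable(config$envPath),
       cladeMap = if (!is.null(config$cladeMapPath)) readCladeMap(config$cladeMapPath),
       observedLat = if (!is.null(config$observedLatPath))
         readObservedLatitudes(config$observedLatPath),
       synthetic = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes CSV outputs
#' plus a JSON manifest to `config$outDir`: `diversity.csv` (per-cell SR,
#' PD, PE, TILD), `restricted_counts.csv` (per-depth totals and
#' south/north-restricted lineage counts with shares), `lineage_ranges.csv`
#' (per-depth latitudinal range of every lineage), `nestedness.csv`
#' (per-depth observed vs null turnover with p-values and verdicts),
#' `correlations.csv` (index x predictor Pearson table, when an environment
#' table is available), `clade_pd_bins.csv` and `clade_pd_depth.csv` (clade
#' contributions, when a clade map is available), and `manifest.json`
#' (config echo, seeds, package version, row counts — no timestamps, so a
#' fixed seed reproduces every output byte for byte). If a stage fails,
#' files written so far are moved to a `quarantine/` subdirectory and the
#' error names the stage.
#'
#' @param config a [pipelineConfig()] (or path to a YAML file for
#'   [readPipelineConfig()]).
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stageName <- "setup"
  emit <- function(df, file) {
    path <- file.path(config$outDir, file)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  res <- tryCatch({
    stageName <- "inputs"
    inp <- .loadInputs(config)
    counts <- list(cellsIn = nCells(inp$grid), speciesIn = nSpecies(inp$grid))

    stageName <- "filter"
    grid <- filterLowRichness(inp$grid, minSR = config$minRichness)
    counts$cellsDroppedByRichnessFilter <- counts$cellsIn - nCells(grid)
    if (config$clipObserved) {
      if (is.null(inp$observedLat))
        stop("clipObserved = TRUE but no observed latitudes supplied")
      grid <- clipToObservedLatitudes(grid, inp$observedLat)
    }
    counts$cellsRetained <- nCells(grid)
    counts$speciesRetained <- nSpecies(grid)
    message("filter: ", counts$cellsRetained, "/", counts$cellsIn,
            " cells retained")

    stageName <- "diversity"
    div <- diversityTable(inp$tree, grid,
                          includeRootPath = config$includeRootPath)
    emit(div, "diversity.csv")

    stageName <- "slice"
    T <- rootAge(inp$tree)
    maxDepth <- if (is.null(config$maxDepth)) T else config$maxDepth
    depths <- seq(config$sliceInterval, maxDepth, by = config$sliceInterval)
    if (length(depths) == 0 || max(depths) < maxDepth - 1e-9)
      depths <- c(depths, maxDepth)
    restricted <- restrictedShare(do.call(rbind, lapply(depths, function(t)
      countRestricted(inp$tree, grid, t, threshold = config$thresholdLat))))
    emit(restricted, "restricted_counts.csv")
    ranges <- do.call(rbind, lapply(depths, function(t) {
      rg <- lineageLatitudinalRanges(inp$tree, grid, t)
      cbind(age = t, rg)
    }))
    emit(ranges, "lineage_ranges.csv")

    stageName <- "nestedness"
    nest <- nestednessTest(inp$tree, grid, depths = depths,
                           binWidth = config$binWidth,
                           replicates = config$replicates,
                           seed = config$seed,
                           fillEmbedded = config$fillEmbedded,
                           adjacentOnly = config$adjacentOnly)
    emit(nest, "nestedness.csv")

    corr <- NULL
    if (!is.null(inp$env)) {
      stageName <- "correlates"
      corr <- correlateDiversityEnv(div, inp$env)
      emit(corr, "correlations.csv")
    }

    cladeBins <- cladeDepth <- NULL
    if (!is.null(inp$cladeMap)) {
      stageName <- "contributions"
      cladeBins <- rbind(
        cbind(level = "superorder",
              cladePDByBin(inp$tree, grid, inp$cladeMap, "superorder",
                           width = config$binWidth)),
        cbind(level = "family",
              cladePDByBin(inp$tree, grid, inp$cladeMap, "family",
                           width = config$binWidth)))
      emit(cladeBins, "clade_pd_bins.csv")
      cladeDepth <- cladePDByDepth(inp$tree, grid, inp$cladeMap, "superorder",
                                   depths = c(0, depths))
      emit(cladeDepth, "clade_pd_depth.csv")
    }

    stageName <- "manifest"
    manifest <- list(
      package = "phylogradient",
      version = as.character(utils::packageVersion("phylogradient")),
      seed = config$seed,
      config = .serializableConfig(config),
      counts = c(counts, list(
        depths = depths,
        rows = list(diversity = nrow(div), restricted = nrow(restricted),
                    lineageRanges = nrow(ranges), nestedness = nrow(nest),
                    correlations = if (is.null(corr)) 0 else nrow(corr)))))
    manifestPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifestPath)

    list(diversity = div, restricted = restricted, ranges = ranges,
         nestedness = nest, correlations = corr, cladeBins = cladeBins,
         cladeDepth = cladeDepth, grid = grid, tree = inp$tree,
         outDir = config$outDir, files = written)
  }, error = function(e) {
    q <- file.path(config$outDir, "quarantine")
    if (length(written)) {
      dir.create(q, showWarnings = FALSE)
      file.rename(written, file.path(q, basename(written)))
    }
    stop("pipeline stage '", stageName, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# config echo safe for JSON (drop classes, NULLs, and the caller-chosen
# output path so identical seeds give byte-identical manifests)
.serializableConfig <- function(config) {
  x <- unclass(config)
  x$outDir <- NULL
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  x[!vapply(x, is.null, logical(1))]
}
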