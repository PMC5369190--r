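# Named experiment presets tying the modules together, plus file-level
# scoring/analysis helpers used by the command-line wrapper in
# inst/scripts/code-landscape.R.

#' Experiment presets
#'
#' Named, fully specified experimental conditions. GA presets run 10
#' independent runs of 1000 individuals for 100 generations (swap 0.5,
#' mutation 0.01 per position, tournament 3%, elitism); sampling presets
#' score large uniform random-code samples.
#'
#' \itemize{
#'   \item \code{table2-nosharing}, \code{table2-sigma001},
#'     \code{table2-sigma01}: restrictive model, MS.
#'   \item \code{table3-nosharing}, \code{table3-sigma001},
#'     \code{table3-sigma01}: unrestrictive model, MS.
#'   \item \code{tms-restrictive-nosharing},
#'     \code{tms-unrestrictive-nosharing}: the tMS weighting.
#'   \item \code{statistical-1M}: 1e6 random restrictive codes under MS.
#'   \item \code{random-10k-restrictive}, \code{random-10k-unrestrictive}:
#'     1e4-code reference samples used for p.d.m. estimation.
#' }
#'
#' @return Named list; each element is either
#'   \code{list(type = "ga", config = GAConfig)} or
#'   \code{list(type = "sample", model, scheme, n)}.
#' @export
experimentPresets <- function() {
  ga <- function(model, scheme, sigma = NA_real_)
    list(type = "ga",
         config = GAConfig(model = model, scheme = scheme,
                           sigmaShare = sigma))
  smp <- function(model, scheme, n)
    list(type = "sample", model = model, scheme = scheme, n = n)
  list(
    "table2-nosharing" = ga("restrictive", "ms"),
    "table2-sigma001"  = ga("restrictive", "ms", 0.01),
    "table2-sigma01"   = ga("restrictive", "ms", 0.1),
    "table3-nosharing" = ga("unrestrictive", "ms"),
    "table3-sigma001"  = ga("unrestrictive", "ms", 0.01),
    "table3-sigma01"   = ga("unrestrictive", "ms", 0.1),
    "tms-restrictive-nosharing"   = ga("restrictive", "tms"),
    "tms-unrestrictive-nosharing" = ga("unrestrictive", "tms"),
    "statistical-1M" = smp("restrictive", "ms", 1000000L),
    "random-10k-restrictive" = smp("restrictive", "ms", 10000L),
    "random-10k-unrestrictive" = smp("unrestrictive", "ms", 10000L))
}

#' Run a named experiment
#'
#' Executes a preset (see \code{\link{experimentPresets}}) and writes its
#' artifacts under \code{outDir}: per-run generation statistics CSV, final
#' population files, the best code table, an aggregate JSON, and a
#' manifest JSON recording the configuration, seeds and package version.
#' With the same master seed the outputs are byte-identical across
#' invocations.
#'
#' @param preset Preset name.
#' @param outDir Output directory (created if needed).
#' @param seed Master seed override (defaults to the preset's).
#' @return Invisibly, a list with the computed results and file paths.
#' @export
runExperiment <- function(preset, outDir, seed = NULL) {
  presets <- experimentPresets()
  if (!preset %in% names(presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spec <- presets[[preset]]
  ver <- as.character(utils::packageVersion("codeAdapt"))
  if (spec$type == "sample") {
    if (!is.null(seed)) set.seed(seed) else set.seed(1L)
    res <- sampleRandomStatistics(spec$model, spec$scheme, spec$n)
    sumPath <- file.path(outDir, "summary.json")
    jsonlite::write_json(
      res[c("mean", "sd", "countBetter", "canonicalCost", "n",
            "model", "scheme")],
      sumPath, auto_unbox = TRUE, digits = NA)
    manifest <- list(preset = preset, type = "sample", seed = seed,
                     version = ver)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(result = res, files = sumPath)))
  }
  cfg <- spec$config
  if (!is.null(seed)) cfg@rngSeed <- as.integer(seed)
  ens <- multiRun(cfg)
  files <- character(0)
  for (i in seq_along(ens$records)) {
    rec <- ens$records[[i]]
    st <- runStats(rec)
    p1 <- file.path(outDir, sprintf("run%02d_generations.csv", i))
    write.csv(st, p1, row.names = FALSE)
    p2 <- file.path(outDir, sprintf("run%02d_final_population.tsv", i))
    writePopulation(finalPopulation(rec), finalCosts(rec), p2)
    files <- c(files, p1, p2)
  }
  best <- which.min(vapply(ens$records, bestCost, numeric(1)))
  bg <- bestGenotype(ens$records[[best]])
  bestMap <- if (length(bg) == 20L) expandCode(bg) else bg
  p3 <- file.path(outDir, "best_code.tsv")
  writeCodeTable(bestMap, p3)
  p4 <- file.path(outDir, "aggregate.json")
  jsonlite::write_json(
    list(condition = ens$aggregate$condition[1L],
         bestFitness = list(mean = ens$aggregate$mean[1L],
                            sd = ens$aggregate$sd[1L]),
         averageFitness = list(mean = ens$aggregate$mean[2L],
                               sd = ens$aggregate$sd[2L]),
         bestOverall = min(vapply(ens$records, bestCost, numeric(1)))),
    p4, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    preset = preset, type = "ga", version = ver,
    masterSeed = cfg@rngSeed,
    runSeeds = vapply(ens$records, function(r) r@seed, integer(1)),
    config = list(
      model = cfg@model, scheme = cfg@scheme,
      populationSize = cfg@populationSize, generations = cfg@generations,
      mutationProb = cfg@mutationProb, swapProb = cfg@swapProb,
      tournamentFraction = cfg@tournamentFraction,
      sigmaShare = if (is.na(cfg@sigmaShare)) NULL else cfg@sigmaShare,
      alpha = cfg@alpha, elitism = cfg@elitism,
      seedCanonical = cfg@seedCanonical, nRuns = cfg@nRuns))
  p5 <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, p5, auto_unbox = TRUE, digits = NA)
  invisible(list(ensemble = ens, files = c(files, p3, p4, p5)))
}

#' Score a code table file
#'
#' Reads a code table (see \code{\link{readCodeTable}}), computes its
#' MS or tMS error cost and prints it with 6 decimals.
#'
#' @param path Code table file.
#' @param scheme Weight scheme name.
#' @return The cost, invisibly.
#' @export
scoreCode <- function(path, scheme = c("ms", "tms")) {
  scheme <- match.arg(scheme)
  cost <- msError(readCodeTable(path), scheme)
  cat(sprintf("%.6f\n", cost))
  invisible(cost)
}

#' Analyze a saved final population
#'
#' Reads a population file (see \code{\link{readPopulation}}) and writes
#' the distance-to-canonical scatter and the inter-distance histogram as
#' CSV files under \code{outDir}.
#'
#' @param path Population file.
#' @param scheme Weight scheme for the cost axis.
#' @param outDir Output directory.
#' @return Invisibly, list with the two data.frames and file paths.
#' @export
analyzePopulationFile <- function(path, scheme = c("ms", "tms"), outDir) {
  scheme <- match.arg(scheme)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  snap <- readPopulation(path)
  sc <- distancesToCanonical(snap$population, scheme)
  hg <- interdistanceHistogram(snap$population)
  p1 <- file.path(outDir, "distance_scatter.csv")
  p2 <- file.path(outDir, "interdistance_histogram.csv")
  write.csv(sc, p1, row.names = FALSE)
  write.csv(hg, p2, row.names = FALSE)
  invisible(list(scatter = sc, histogram = hg, files = c(p1, p2)))
}

#' Read a GA configuration from a flat key:value file
#'
#' Parses a flat YAML file whose keys mirror the \code{\link{GAConfig}}
#' constructor arguments (e.g. \code{model: unrestrictive},
#' \code{sigmaShare: 0.1}, \code{rngSeed: 42}). Keys given in
#' \code{overrides} take precedence over the file, mirroring how
#' command-line flags override a configuration file. Unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A validated \code{GAConfig}.
#' @export
gaConfigFromFile <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(GAConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(GAConfig, vals)
}
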