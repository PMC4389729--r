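#' Default run configuration
#'
#' The defaults reproduce the reference settings of the screening
#' protocol: 12-min sampling, second-order reference model, OD 0.6
#' readout threshold, alpha 0.05, and the 0.01--10 mM IPTG series.
#'
#' @return Nested list of configuration values; see the bundled
#'   \code{extdata/default-config.yaml} for the file form.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    output_dir = "malonyl-sensor-run",
    generator = list(
      constructs = c("matCmatB", "matCatoDA"),
      iptg_mM = c(0.01, 0.1, 0.3, 0.6, 1, 10),
      replicates = 3L,
      arabinose_pct = 0.01,
      substrate = FALSE,
      sigma = 0.02,
      well_cv = 0,
      n_times = 120L,
      Ts = 12,
      growth = paramList(GrowthParams()),
      sensor = paramList(SensorParams()),
      vm_map = paramList(InductionMap())),
    identification = list(order = 2L),
    analysis = list(od_threshold = 0.6, od_floor = 0.05, alpha = 0.05))
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it (recursively) over
#' [defaultRunConfig()], so a config file only needs to state what it
#' changes.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return Nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  mergeConfig(cfg, user)
}

mergeConfig <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- mergeConfig(base[[k]], over[[k]])
    else
      base[[k]] <- over[[k]]
  }
  base
}

cfgGrowth <- function(g) do.call(GrowthParams, g$growth)
cfgSensor <- function(g) do.call(SensorParams, g$sensor)
cfgVmMap <- function(g) do.call(InductionMap, g$vm_map)

#' Run the simulation stage
#'
#' Generates a synthetic plate from the configuration and writes
#' \code{plate.csv} (plus its YAML parameter sidecar) into the output
#' directory.
#'
#' @param config configuration list from [readRunConfig()].
#' @param seed optional seed overriding the configured one.
#' @return Invisibly, the generated [PlateTimeSeries-class].
#' @export
runSimulate <- function(config = defaultRunConfig(), seed = NULL) {
  g <- config$generator
  if (is.null(seed)) seed <- config$seed
  design <- defaultPlateDesign(g$constructs, iptg = g$iptg_mM,
                               replicates = g$replicates,
                               arabinose = g$arabinose_pct,
                               substrate = g$substrate)
  plate <- generatePlate(design, growth = cfgGrowth(g),
                         sensor = cfgSensor(g), vmMap = cfgVmMap(g),
                         sigma = g$sigma, seed = seed,
                         time = seq(0, by = g$Ts,
                                    length.out = g$n_times),
                         wellCV = g$well_cv)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  writePlateCsv(plate, file.path(config$output_dir, "plate.csv"))
  invisible(plate)
}

#' Run the identification stage
#'
#' Reads the plate CSV and writes the per-well parameter table
#' \code{fits.csv} (gain, time constants, diagnostics; the
#' machine-readable analogue of a per-construct parameter table).
#'
#' @inheritParams runSimulate
#' @param plateFile plate CSV; defaults to \code{plate.csv} in the output
#'   directory.
#' @return Invisibly, the fits data.frame.
#' @export
runIdentify <- function(config = defaultRunConfig(),
                        plateFile = file.path(config$output_dir,
                                              "plate.csv")) {
  plate <- readPlateCsv(plateFile)
  fits <- identifyPlate(plate, order = config$identification$order)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  writeResultsCsv(fits, file.path(config$output_dir, "fits.csv"))
  invisible(fits)
}

#' Run the response-analysis stage
#'
#' Computes OD-anchored readouts (\code{readouts.csv}), per-construct
#' dose-response curves (\code{dose_response.csv}), replicate CVs per
#' condition (\code{cv.csv}) and, when an identification table is
#' available, parameter-induction correlations
#' (\code{correlations.csv}).
#'
#' @inheritParams runIdentify
#' @param fitsFile optional fits CSV from [runIdentify()].
#' @return Invisibly, a list of the computed tables.
#' @export
runAnalyze <- function(config = defaultRunConfig(),
                       plateFile = file.path(config$output_dir,
                                             "plate.csv"),
                       fitsFile = file.path(config$output_dir,
                                            "fits.csv")) {
  plate <- readPlateCsv(plateFile)
  a <- config$analysis
  readouts <- plateReadouts(plate, odThreshold = a$od_threshold)
  dr <- do.call(rbind, lapply(split(readouts, readouts$construct),
    function(g) {
      ok <- !g$no_growth
      if (length(unique(g$iptg_mM[ok])) < 2) return(NULL)
      cbind(construct = g$construct[1],
            doseResponse(g$fluorescence_at_od[ok], g$iptg_mM[ok]))
    }))
  rownames(dr) <- NULL
  cv <- do.call(rbind, lapply(
    split(readouts, list(readouts$construct, readouts$iptg_mM),
          drop = TRUE),
    function(g) {
      v <- g$fluorescence_at_od[!g$no_growth]
      data.frame(construct = g$construct[1], iptg_mM = g$iptg_mM[1],
                 cv = if (length(v) >= 2 && mean(v) > 0) replicateCV(v)
                      else NA_real_, n = length(v))
    }))
  rownames(cv) <- NULL
  out <- list(readouts = readouts, doseResponse = dr, cv = cv)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  writeResultsCsv(readouts, file.path(config$output_dir, "readouts.csv"))
  writeResultsCsv(dr, file.path(config$output_dir, "dose_response.csv"))
  writeResultsCsv(cv, file.path(config$output_dir, "cv.csv"))
  if (!is.null(fitsFile) && file.exists(fitsFile)) {
    fits <- read.csv(fitsFile)
    corr <- try(paramInductionCorrelation(fits), silent = TRUE)
    if (!inherits(corr, "try-error")) {
      out$correlations <- corr$correlations
      out$tauByConstruct <- corr$tauByConstruct
      writeResultsCsv(corr$correlations,
                      file.path(config$output_dir, "correlations.csv"))
      writeResultsCsv(corr$tauByConstruct,
                      file.path(config$output_dir,
                                "tau_by_construct.csv"))
    }
  }
  invisible(out)
}

#' Run the full pipeline
#'
#' Simulate, identify and analyze in sequence with one seed; every output
#' byte is determined by the configuration and the seed.
#'
#' @inheritParams runSimulate
#' @return Invisibly, the list from [runAnalyze()].
#' @export
runReport <- function(config = defaultRunConfig(), seed = NULL) {
  runSimulate(config, seed = seed)
  runIdentify(config)
  runAnalyze(config)
}
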