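#' Build a factorial plate design
#'
#' Expands constructs x IPTG doses x replicates into a well-level design
#' table, assigning standard 96-well coordinates (A1..H12) while they
#' last and synthetic ids beyond.
#'
#' @param constructs character vector of construct labels.
#' @param iptg IPTG doses (mM); defaults to the screening series
#'   0.01, 0.1, 0.3, 0.6, 1, 10 mM.
#' @param replicates replicate cultures per condition.
#' @param arabinose arabinose dose (percent) applied plate-wide; the
#'   optimization screens settled on 0.01\%.
#' @param substrate logical, substrate supplementation plate-wide, or a
#'   vector recycled over rows.
#' @return data.frame with columns well_id, construct, iptg_mM,
#'   arabinose_pct, substrate, replicate.
#' @examples
#' d <- defaultPlateDesign("matCmatB", replicates = 2)
#' nrow(d)  # 12 wells
#' @export
defaultPlateDesign <- function(constructs,
                               iptg = c(0.01, 0.1, 0.3, 0.6, 1, 10),
                               replicates = 3, arabinose = 0.01,
                               substrate = FALSE) {
  g <- expand.grid(replicate = seq_len(replicates), iptg_mM = iptg,
                   construct = constructs, stringsAsFactors = FALSE)
  n <- nrow(g)
  std <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  ids <- if (n <= 96) std[seq_len(n)] else sprintf("W%03d", seq_len(n))
  data.frame(well_id = ids, construct = g$construct, iptg_mM = g$iptg_mM,
             arabinose_pct = arabinose,
             substrate = rep_len(substrate, n),
             replicate = as.integer(g$replicate))
}

#' Generate a synthetic plate-reader run
#'
#' Simulates a kinetic microplate screen with the structure the analysis
#' assumes: every well grows along a logistic biomass curve which drives
#' the mechanistic sensor cascade; the IPTG dose sets the malonyl-CoA
#' production rate vm through a Hill map (and, optionally, arabinose sets
#' the FapR level through a second map); multiplicative Gaussian
#' measurement noise is added to both channels and clipped at zero.
#' Identical seed and design give bitwise-identical output.
#'
#' @param design well-level design table as from [defaultPlateDesign()].
#' @param growth a [GrowthParams-class] shared by all wells.
#' @param sensor a [SensorParams-class]; its \code{vm} and \code{fapR}
#'   are overridden per well by the induction maps.
#' @param vmMap [InductionMap-class] from IPTG (mM) to vm.
#' @param fMap optional [InductionMap-class] from arabinose (percent) to
#'   the FapR level; when NULL, \code{sensor@fapR} is used everywhere.
#' @param sigma relative standard deviation of the multiplicative
#'   measurement noise (default 0.02, a typical plate-reader scale).
#' @param seed integer seed; required, making runs reproducible.
#' @param time uniform time grid (min); defaults to 120 readings every
#'   12 min (24 h).
#' @param wellCV lognormal coefficient of variation applied per well to
#'   vm, emulating clone-to-clone variation (default 0: replicates differ
#'   only by measurement noise).
#' @param substrateGain multiplicative effect of substrate supplementation
#'   on vm; a scalar, or a named vector by construct (values below 1
#'   emulate the hindrance seen for some pathways).
#' @param sensors optional named list of [SensorParams-class] by
#'   construct, giving constructs distinct kinetics (hence distinct time
#'   constants).
#' @param depletionOD optional OD at which the FapR level drops to
#'   \code{depletionFactor} of its value, emulating derepression when
#'   arabinose is catabolized at the end of growth; NULL (default)
#'   disables the scenario.
#' @param depletionFactor multiplier on FapR past \code{depletionOD}.
#' @return A [PlateTimeSeries-class]; generator parameters and the seed
#'   are stored in its metadata.
#' @examples
#' p <- generatePlate(defaultPlateDesign("matCmatB", replicates = 1),
#'                    seed = 1, time = seq(0, by = 12, length.out = 60))
#' dim(odMatrix(p))
#' @export
generatePlate <- function(design, growth = GrowthParams(),
                          sensor = SensorParams(),
                          vmMap = InductionMap(), fMap = NULL,
                          sigma = 0.02, seed,
                          time = seq(0, by = 12, length.out = 120),
                          wellCV = 0, substrateGain = 1, sensors = NULL,
                          depletionOD = NULL, depletionFactor = 0.25) {
  if (is.null(design) || nrow(design) == 0) stop("empty plate design")
  miss <- setdiff(.wellColumns, colnames(design))
  if (length(miss))
    stop("design lacks columns: ", paste(miss, collapse = ", "))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (length(sigma) != 1L || sigma < 0) stop("'sigma' must be >= 0")
  checkTimeGrid(time)
  validObject(growth); validObject(sensor); validObject(vmMap)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  X <- logisticGrowth(growth, time)
  dX <- logisticGrowthRate(growth, time)
  nT <- length(time)
  nW <- nrow(design)
  od <- matrix(0, nT, nW)
  rfp <- matrix(0, nT, nW)
  for (i in seq_len(nW)) {
    sp <- sensor
    if (!is.null(sensors) && design$construct[i] %in% names(sensors))
      sp <- sensors[[design$construct[i]]]
    vm <- inductionToRate(design$iptg_mM[i], vmMap)
    if (isTRUE(design$substrate[i])) {
      gainS <- if (!is.null(names(substrateGain)))
        substrateGain[[design$construct[i]]] else substrateGain
      vm <- vm * gainS
    }
    if (wellCV > 0)
      vm <- vm * exp(rnorm(1, 0, sqrt(log(1 + wellCV^2))))
    sp@vm <- vm
    if (!is.null(fMap))
      sp@fapR <- inductionToRate(design$arabinose_pct[i], fMap)

    R <- simulateWellCascade(sp, X, dX, time, depletionOD, depletionFactor)

    odNoise <- if (sigma > 0) 1 + sigma * rnorm(nT) else rep(1, nT)
    rfpNoise <- if (sigma > 0) 1 + sigma * rnorm(nT) else rep(1, nT)
    od[, i] <- pmax(X * odNoise, 0)
    rfp[, i] <- pmax(R * rfpNoise, 0)
  }

  meta <- list(generator = list(
    seed = seed, sigma = sigma, wellCV = wellCV,
    substrateGain = substrateGain, Ts = if (nT > 1) time[2] - time[1] else NA,
    growth = paramList(growth), sensor = paramList(sensor),
    vmMap = paramList(vmMap),
    fMap = if (is.null(fMap)) NULL else paramList(fMap),
    depletionOD = depletionOD, depletionFactor = depletionFactor))
  PlateTimeSeries(time, od, rfp, design, metadata = meta)
}

## cascade for one well, with the optional FapR-depletion scenario
simulateWellCascade <- function(sp, X, dX, time, depletionOD,
                                depletionFactor) {
  if (is.null(depletionOD) || !any(X >= depletionOD))
    return(simulateSensorCascade(sp, X, time, dbiomass = dX)$R)
  k0 <- which(X >= depletionOD)[1]
  if (k0 < 3)
    return(simulateSensorCascade(withFapR(sp, sp@fapR * depletionFactor),
                                 X, time, dbiomass = dX)$R)
  seg1 <- simulateSensorCascade(sp, X[1:k0], time[1:k0],
                                dbiomass = dX[1:k0])
  init <- c(M = seg1$M[k0], C = seg1$C[k0], R = seg1$R[k0])
  sp2 <- withFapR(sp, sp@fapR * depletionFactor)
  seg2 <- simulateSensorCascade(sp2, X[k0:length(X)], time[k0:length(X)],
                                dbiomass = dX[k0:length(X)], init = init)
  c(seg1$R, seg2$R[-1])
}

withFapR <- function(sp, value) { sp@fapR <- value; sp }

## slots of a parameter object as a plain list (for the config sidecar)
paramList <- function(object) {
  out <- lapply(slotNames(object), function(s) slot(object, s))
  names(out) <- slotNames(object)
  out
}
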