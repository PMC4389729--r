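#' Fluorescence readout at an OD threshold
#'
#' Interpolates the fluorescence at the first upward crossing of the OD
#' threshold, anchoring every well's readout to the same growth phase
#' (log phase at OD 0.6 by default) and so avoiding the late-growth
#' derepression artifact. Later crossings are ignored.
#'
#' @param od,rfp aligned OD and fluorescence series.
#' @param time measurement times (min).
#' @param odThreshold OD600 threshold (default 0.6).
#' @return list with \code{fluorescence} (linearly interpolated at the
#'   crossing) and \code{crossingTime} (min).
#' @examples
#' readoutAtOD(c(0.5, 0.7), c(100, 200), c(0, 12))  # 150 at t = 6
#' @export
readoutAtOD <- function(od, rfp, time, odThreshold = 0.6) {
  n <- length(od)
  if (length(rfp) != n || length(time) != n)
    stop("'od', 'rfp' and 'time' must be aligned")
  if (od[1] >= odThreshold)
    stop("OD series must begin below the threshold")
  above <- which(od >= odThreshold)
  if (!length(above))
    stop(sprintf("no growth: OD never reaches %g", odThreshold))
  k <- above[1]
  if (od[k] == odThreshold || k == 1)
    return(list(fluorescence = rfp[k], crossingTime = time[k]))
  w <- (odThreshold - od[k - 1]) / (od[k] - od[k - 1])
  list(fluorescence = rfp[k - 1] + w * (rfp[k] - rfp[k - 1]),
       crossingTime = time[k - 1] + w * (time[k] - time[k - 1]))
}

#' Growth-phase readouts for every well of a plate
#'
#' Applies [readoutAtOD()] well-wise; wells that never reach the
#' threshold (no growth upon induction) get NA readouts and are flagged.
#'
#' @param plate a [PlateTimeSeries-class].
#' @param odThreshold OD600 threshold (default 0.6).
#' @return data.frame: well metadata plus \code{fluorescence_at_od},
#'   \code{crossing_time_min} and logical \code{no_growth}.
#' @export
plateReadouts <- function(plate, odThreshold = 0.6) {
  stopifnot(is(plate, "PlateTimeSeries"))
  wells <- wellInfo(plate)
  od <- odMatrix(plate)
  rfp <- rfpMatrix(plate)
  tg <- timeGrid(plate)
  out <- wells[, .wellColumns, drop = FALSE]
  out$fluorescence_at_od <- NA_real_
  out$crossing_time_min <- NA_real_
  out$no_growth <- FALSE
  for (i in seq_len(nrow(wells))) {
    r <- try(readoutAtOD(od[, i], rfp[, i], tg, odThreshold),
             silent = TRUE)
    if (inherits(r, "try-error")) {
      out$no_growth[i] <- TRUE
    } else {
      out$fluorescence_at_od[i] <- r$fluorescence
      out$crossing_time_min[i] <- r$crossingTime
    }
  }
  rownames(out) <- NULL
  out
}

#' OD-normalized fluorescence with a low-OD mask
#'
#' Elementwise RFP/OD ratio; samples with OD below \code{odFloor} are
#' masked (NA) rather than allowed to blow up, so the early low-biomass
#' portion of the run does not dominate. The characteristic early dip of
#' RFP/OD when reporter expression lags growth survives normalization.
#'
#' @param od,rfp aligned series, or a [PlateTimeSeries-class] in
#'   \code{od} (then \code{rfp} is ignored and a matrix is returned).
#' @param odFloor mask threshold (OD units, default 0.05).
#' @return Numeric vector (or time x wells matrix) of RFP/OD with NA
#'   below the floor.
#' @export
normalizeRfpOd <- function(od, rfp = NULL, odFloor = 0.05) {
  if (is(od, "PlateTimeSeries")) {
    plate <- od
    odm <- odMatrix(plate)
    out <- rfpMatrix(plate) / odm
    out[odm < odFloor] <- NA_real_
    return(out)
  }
  if (length(rfp) != length(od)) stop("'od' and 'rfp' must be aligned")
  out <- rfp / od
  out[od < odFloor] <- NA_real_
  out
}

#' Dose-response curve from well readouts
#'
#' Per-concentration mean, standard deviation and replicate count of a
#' readout (typically the OD-anchored fluorescence), ordered by
#' increasing dose.
#'
#' @param readouts numeric readout per well.
#' @param dose inducer concentration per well (mM).
#' @return data.frame with columns \code{dose}, \code{mean}, \code{sd}
#'   (0 for single replicates), \code{n}.
#' @export
doseResponse <- function(readouts, dose) {
  if (length(readouts) != length(dose))
    stop("'readouts' and 'dose' must be aligned")
  keep <- is.finite(readouts) & is.finite(dose)
  readouts <- readouts[keep]
  dose <- dose[keep]
  lev <- sort(unique(dose))
  if (length(lev) < 2)
    stop("dose-response needs at least two inducer concentrations")
  out <- data.frame(dose = lev, mean = NA_real_, sd = NA_real_,
                    n = NA_integer_)
  for (i in seq_along(lev)) {
    v <- readouts[dose == lev[i]]
    out$mean[i] <- mean(v)
    out$sd[i] <- if (length(v) > 1) sd(v) else 0
    out$n[i] <- length(v)
  }
  out
}

#' Pearson correlation with a t-distributed p-value
#'
#' Sample Pearson correlation between two vectors with the usual
#' two-sided t-test on n - 2 degrees of freedom (via
#' \code{stats::cor.test}).
#'
#' @param x,y numeric vectors, n >= 3, each with nonzero variance.
#' @return list with \code{r}, \code{pValue} and \code{n}.
#' @export
pearsonR <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pValue = ct$p.value, n = length(x))
}

#' Correlation of fitted sensor parameters with induction
#'
#' For a table of per-well identification results across IPTG doses,
#' correlates each parameter (K, tau_1, tau_2, tau_z) with log10(dose) --
#' doses span three decades, so the log scale is the natural axis. A
#' responsive, robust sensor shows gain strongly correlated with dose
#' while time constants are not. Also returns the per-construct
#' dispersion of the time constants for the clustering assessment.
#'
#' @param fits data.frame as from [identifyPlate()] (columns iptg_mM,
#'   construct, K, tau_1, tau_2, tau_z).
#' @return list with \code{correlations} (data.frame parameter, r,
#'   p_value, n) and \code{tauByConstruct} (data.frame construct,
#'   parameter, mean, sd, n).
#' @export
paramInductionCorrelation <- function(fits) {
  need <- c("iptg_mM", "construct", "K", "tau_1", "tau_2", "tau_z")
  miss <- setdiff(need, colnames(fits))
  if (length(miss))
    stop("fits lack columns: ", paste(miss, collapse = ", "))
  if (length(unique(fits$iptg_mM[is.finite(fits$K)])) < 4)
    stop("need fits from at least 4 induction levels")
  ld <- log10(fits$iptg_mM)
  pars <- c("K", "tau_1", "tau_2", "tau_z")
  cors <- do.call(rbind, lapply(pars, function(p) {
    v <- fits[[p]]
    res <- try(pearsonR(ld, v), silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(parameter = p, r = NA_real_, p_value = NA_real_,
                 n = sum(is.finite(v) & is.finite(ld)))
    else
      data.frame(parameter = p, r = res$r, p_value = res$pValue,
                 n = res$n)
  }))
  disp <- do.call(rbind, lapply(split(fits, fits$construct), function(g) {
    do.call(rbind, lapply(c("tau_1", "tau_2"), function(p) {
      v <- g[[p]][is.finite(g[[p]])]
      data.frame(construct = g$construct[1], parameter = p,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 n = length(v))
    }))
  }))
  rownames(disp) <- NULL
  list(correlations = cors, tauByConstruct = disp)
}

#' Test the effect of substrate supplementation
#'
#' Two-sample Welch (unequal-variance) t-test between readouts obtained
#' with and without the substrate of the production pathway; the effect
#' can be a boost or a hindrance, so the direction of the mean difference
#' is reported alongside significance.
#'
#' @param with readouts with substrate supplementation (n >= 2).
#' @param without readouts without (n >= 2).
#' @param alpha significance level (default 0.05).
#' @return list with \code{pValue}, \code{significant} (p < alpha),
#'   \code{direction} (sign of mean(with) - mean(without)) and
#'   \code{meanDifference}.
#' @export
substrateEffectTest <- function(with, without, alpha = 0.05) {
  if (length(with) < 2 || length(without) < 2)
    stop("need at least 2 replicates per group")
  tt <- t.test(with, without, var.equal = FALSE)
  d <- mean(with) - mean(without)
  list(pValue = tt$p.value, significant = tt$p.value < alpha,
       direction = sign(d), meanDifference = d)
}

#' Coefficient of variation across replicates
#'
#' Sample (n - 1) standard deviation divided by the mean; the
#' reproducibility metric for replicate cultures.
#'
#' @param x replicate readouts, n >= 2, positive mean.
#' @return CV as a single number.
#' @examples
#' replicateCV(c(90, 110))  # 0.1414
#' @export
replicateCV <- function(x) {
  if (length(x) < 2) stop("need at least 2 replicates")
  m <- mean(x)
  if (m <= 0) stop("CV undefined: mean must be positive")
  sd(x) / m
}
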