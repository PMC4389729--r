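#' Logistic biomass curve with lag
#'
#' Evaluates a lagged logistic growth curve on a time grid. Biomass stays
#' at \code{X0} during the lag phase, then follows
#' \deqn{X(t) = X_{max} / (1 + (X_{max}/X_0 - 1) e^{-\mu (t - lag)}),}
#' which is non-decreasing and bounded by the carrying capacity.
#'
#' @param params a [GrowthParams-class].
#' @param time numeric vector of times (min), uniformly spaced, non-empty.
#' @return Numeric vector of biomass (OD600) on \code{time}.
#' @seealso [logisticGrowthRate()] for the analytic derivative.
#' @examples
#' gp <- GrowthParams(X0 = 0.05, Xmax = 1, mu = 0.02, lag = 0)
#' logisticGrowth(gp, c(0, log(19) / 0.02))  # start and midpoint
#' @export
logisticGrowth <- function(params, time) {
  stopifnot(is(params, "GrowthParams"))
  validObject(params)
  checkTimeGrid(time)
  tt <- pmax(time - params@lag, 0)
  params@Xmax / (1 + (params@Xmax / params@X0 - 1) * exp(-params@mu * tt))
}

#' Analytic derivative of the logistic biomass curve
#'
#' dX/dt of [logisticGrowth()]; zero during the lag phase, then
#' mu * X * (1 - X/Xmax). Used for the dX/dt terms of the sensor cascade
#' and of the transfer models, avoiding finite-difference noise.
#'
#' @inheritParams logisticGrowth
#' @return Numeric vector of growth rates (OD/min) on \code{time}.
#' @export
logisticGrowthRate <- function(params, time) {
  stopifnot(is(params, "GrowthParams"))
  X <- logisticGrowth(params, time)
  ifelse(time < params@lag, 0, params@mu * X * (1 - X / params@Xmax))
}

#' Map inducer concentration to a model rate
#'
#' Hill response \code{basal + vmax * I^n / (Kh^n + I^n)}; monotone
#' non-decreasing, bounded between basal and basal + vmax.
#'
#' @param inducer inducer concentration(s), >= 0 (mM for IPTG, percent for
#'   arabinose).
#' @param map an [InductionMap-class].
#' @return Numeric vector of mapped rates.
#' @examples
#' m <- InductionMap(basal = 1, vmax = 4, Kh = 0.3, n = 1)
#' inductionToRate(c(0, 0.3, 1e6), m)  # basal, basal + vmax/2, ~basal + vmax
#' @export
inductionToRate <- function(inducer, map) {
  stopifnot(is(map, "InductionMap"))
  validObject(map)
  if (any(!is.finite(inducer)) || any(inducer < 0))
    stop("'inducer' must be finite and >= 0")
  hill <- ifelse(inducer == 0, 0,
                 inducer^map@n / (map@Kh^map@n + inducer^map@n))
  map@basal + map@vmax * hill
}

## shared grid check (internal)
checkTimeGrid <- function(time) {
  if (length(time) == 0 || any(!is.finite(time)))
    stop("time grid must be non-empty and finite")
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0))
      stop("time grid must be strictly increasing")
    if (diff(range(dt)) > 1e-8 * mean(dt))
      stop("time grid must be uniformly spaced")
  }
  invisible(time)
}
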