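#' Simulate the mechanistic biosensor cascade
#'
#' Integrates the three-stage sensor model driven by a biomass curve X(t):
#' \deqn{dM/dt = v_m X - v_g dX/dt - \gamma_m M}
#' \deqn{dC/dt = k_f F M - k_r C}
#' \deqn{dR/dt = \kappa C - \gamma_r R}
#' where M is malonyl-CoA, C the FapR--malonyl-CoA complex and R the
#' fluorescent reporter. With vg = 0 and non-negative inputs all states
#' stay non-negative.
#'
#' Integration uses \code{deSolve::lsoda} (adaptive, stiff-capable) at
#' rtol 1e-8, since the binding rate kf * F can be much faster than the
#' other rates.
#'
#' @param sensor a [SensorParams-class].
#' @param biomass numeric biomass series on \code{time}, or a
#'   [GrowthParams-class] (then the analytic derivative is used).
#' @param time uniform time grid (min).
#' @param dbiomass optional numeric dX/dt series on \code{time}; when
#'   missing and \code{biomass} is numeric, central differences are used
#'   (only needed when vg != 0 or for the transfer-model comparison).
#' @param init named initial state \code{c(M=, C=, R=)}; defaults to zero.
#' @return data.frame with columns \code{time}, \code{M}, \code{C},
#'   \code{R}.
#' @seealso [steadyStateGain()] for the analytic steady-state R/X ratio.
#' @examples
#' sp <- SensorParams(vm = 0.1)
#' out <- simulateSensorCascade(sp, rep(1, 200), seq(0, 4000, by = 12))
#' tail(out$R, 1) / steadyStateGain(sp)  # approaches 1
#' @export
simulateSensorCascade <- function(sensor, biomass, time, dbiomass = NULL,
                                  init = c(M = 0, C = 0, R = 0)) {
  stopifnot(is(sensor, "SensorParams"))
  validObject(sensor)
  checkTimeGrid(time)
  if (is(biomass, "GrowthParams")) {
    gp <- biomass
    Xfun <- function(t) logisticGrowth(gp, t)
    dXfun <- function(t) logisticGrowthRate(gp, t)
  } else {
    if (length(biomass) != length(time))
      stop("'biomass' must be defined on 'time'")
    Xfun <- approxfun(time, biomass, rule = 2)
    if (is.null(dbiomass)) {
      dX <- centralDiff(biomass, time)
    } else {
      if (length(dbiomass) != length(time))
        stop("'dbiomass' must be defined on 'time'")
      dX <- dbiomass
    }
    dXfun <- approxfun(time, dX, rule = 2)
  }
  p <- sensor
  rhs <- function(t, y, parms) {
    X <- Xfun(t)
    dXdt <- dXfun(t)
    list(c(
      M = p@vm * X - p@vg * dXdt - p@gammaM * y[1],
      C = p@kf * p@fapR * y[1] - p@kr * y[2],
      R = p@kappa * y[2] - p@gammaR * y[3]))
  }
  init <- init[c("M", "C", "R")]
  out <- tryCatch(
    deSolve::lsoda(y = init, times = time, func = rhs, parms = NULL,
                   rtol = 1e-8, atol = 1e-12),
    warning = function(w) {
      stop(sprintf(paste0(
        "sensor cascade integration failed (%s); check the magnitudes of ",
        "kf*fapR = %g, kr = %g, gammaM = %g, gammaR = %g relative to the ",
        "time step"), conditionMessage(w), p@kf * p@fapR, p@kr, p@gammaM,
        p@gammaR), call. = FALSE)
    })
  data.frame(time = out[, "time"], M = out[, "M"], C = out[, "C"],
             R = out[, "R"])
}

#' Steady-state gain of the sensor cascade
#'
#' Ratio R/X at equilibrium under constant biomass, obtained by chaining
#' the equilibria of the metabolite balance (M = vm X / gamma_m), the
#' binding reaction (C = F M / Kd) and reporter expression
#' (R = kappa C / gamma_r):
#' \deqn{R/X = \kappa F v_m / (K_d \gamma_m \gamma_r), \quad K_d = k_r/k_f.}
#' This is the sensor's sensitivity: the fluorescence produced per unit of
#' biomass for a given malonyl-CoA production rate, and the quantity the
#' fitted filter gain K estimates.
#'
#' @param sensor a [SensorParams-class] with gammaM, gammaR, Kd > 0.
#' @return The steady-state R/X ratio (fluorescence per OD).
#' @examples
#' steadyStateGain(SensorParams(vm = 2, gammaM = 0.5, kappa = 3,
#'                              gammaR = 1.5, fapR = 1.2, kf = 1, kr = 2.4))
#' @export
steadyStateGain <- function(sensor) {
  stopifnot(is(sensor, "SensorParams"))
  validObject(sensor)
  Kd <- kdConstant(sensor)
  if (sensor@gammaM <= 0 || sensor@gammaR <= 0 || Kd <= 0)
    stop("steady-state gain requires gammaM, gammaR and Kd = kr/kf > 0")
  sensor@kappa * sensor@fapR * sensor@vm /
    (Kd * sensor@gammaM * sensor@gammaR)
}

## central differences with one-sided ends (internal)
centralDiff <- function(x, time) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dt <- time[2] - time[1]
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}
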