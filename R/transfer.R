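#' Simulate an approximate linear sensor model
#'
#' Integrates the continuous state-space form of the selected filter order
#' with zero initial conditions. For order 1,
#' \deqn{\tau_{p1} dR/dt = -R + K (X - \tau_z dX/dt);}
#' orders 2 and 3 cascade one or two additional first-order integral
#' stages between the driven state and the output. The response is linear
#' in the input (superposition holds) and the final value of a step of
#' height c is K * c for every order.
#'
#' @param model a [TransferModel-class].
#' @param input biomass input: a numeric series on \code{time}, a
#'   [GrowthParams-class], or a function of time.
#' @param time uniform time grid (min).
#' @param dinput optional input derivative: a numeric series or function;
#'   when missing it is taken analytically (GrowthParams), or by central
#'   differences (numeric series).
#' @return Numeric fluorescence series R(t) on \code{time}.
#' @seealso [stepResponse()] for the closed-form step response.
#' @examples
#' m <- TransferModel(K = 2, tauP = c(50, 10))
#' tm <- seq(0, 2000, by = 12)
#' r <- simulateTransferModel(m, rep(1, length(tm)), tm)
#' tail(r, 1)  # approaches K = 2
#' @export
simulateTransferModel <- function(model, input, time, dinput = NULL) {
  stopifnot(is(model, "TransferModel"))
  validObject(model)
  checkTimeGrid(time)
  if (is(input, "GrowthParams")) {
    gp <- input
    Xfun <- function(t) logisticGrowth(gp, t)
    dXfun <- function(t) logisticGrowthRate(gp, t)
  } else if (is.function(input)) {
    Xfun <- input
    if (is.null(dinput))
      stop("'dinput' is required when 'input' is a function")
    dXfun <- dinput
  } else {
    if (length(input) != length(time))
      stop("'input' must be defined on 'time'")
    Xfun <- approxfun(time, input, rule = 2)
    dX <- if (is.null(dinput)) centralDiff(input, time) else dinput
    if (length(dX) != length(time))
      stop("'dinput' must be defined on 'time'")
    dXfun <- approxfun(time, dX, rule = 2)
  }
  n <- model@order
  tp <- model@tauP
  K <- model@K
  tz <- model@tauZ
  rhs <- function(t, y, parms) {
    drive <- K * (Xfun(t) - tz * dXfun(t))
    d <- numeric(n)
    d[1] <- (-y[1] + drive) / tp[1]
    if (n > 1) for (i in 2:n) d[i] <- (-y[i] + y[i - 1]) / tp[i]
    list(d)
  }
  out <- deSolve::lsoda(y = numeric(n), times = time, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  as.numeric(out[, n + 1])
}

#' Closed-form step response of a transfer model
#'
#' Analytic response to a step input of height \code{height} applied at
#' t = 0 with zero initial conditions, for tauZ = 0. For distinct poles of
#' an order-2 model this is
#' \deqn{K c \left(1 - \frac{\tau_1 e^{-t/\tau_1} - \tau_2 e^{-t/\tau_2}}
#'   {\tau_1 - \tau_2}\right);}
#' coincident poles switch to the repeated-root form
#' \eqn{K c (1 - (1 + t/\tau) e^{-t/\tau})}, since the lag regression can
#' legitimately return coincident pole estimates.
#'
#' @param model a [TransferModel-class] of order 1 or 2 with tauZ = 0.
#' @param time times (min) at which to evaluate.
#' @param height step height (input units).
#' @return Numeric response series.
#' @export
stepResponse <- function(model, time, height = 1) {
  stopifnot(is(model, "TransferModel"))
  validObject(model)
  if (model@tauZ != 0)
    stop("closed-form step response implemented for tauZ = 0 only")
  K <- model@K
  if (model@order == 1L) {
    tau <- model@tauP[1]
    return(K * height * (1 - exp(-time / tau)))
  }
  if (model@order != 2L)
    stop("closed-form step response implemented for orders 1 and 2")
  t1 <- model@tauP[1]
  t2 <- model@tauP[2]
  if (abs(t1 - t2) < 1e-9 * t1) {
    tau <- (t1 + t2) / 2
    K * height * (1 - (1 + time / tau) * exp(-time / tau))
  } else {
    K * height *
      (1 - (t1 * exp(-time / t1) - t2 * exp(-time / t2)) / (t1 - t2))
  }
}
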