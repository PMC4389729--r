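#' Fit a discrete ARX model by lagged least squares
#'
#' Ordinary least squares of R[k] on its own lags R[k-1..order] and the
#' input lags X[k..k-order], without intercept, using all complete lag
#' rows (the first \code{order} samples are dropped). This is the
#' regression form of the bilinear-discretized filter models.
#'
#' Exactly collinear regressors are tolerated when the pivoted solution
#' still reproduces R perfectly (overparameterized noise-free data, where
#' aliased coefficients are set to 0); otherwise rank deficiency (e.g. a
#' constant input) raises an identifiability error.
#'
#' @param R fluorescence output series.
#' @param X biomass input series, same length.
#' @param order model order (1--3).
#' @param Ts sampling period (min), recorded in the result.
#' @return A list: \code{model} (a [DiscreteARX-class]),
#'   \code{residualVariance} (df-adjusted), \code{rSquared} (in-sample, on
#'   centered R[k]), \code{nSamples} (regression rows).
#' @examples
#' true <- DiscreteARX(a = 0.8, b = c(0.3, 0.1), Ts = 12)
#' x <- logisticGrowth(GrowthParams(lag = 0), seq(0, 1188, by = 12))
#' r <- simulateDiscreteARX(true, x)
#' fitDiscrete(r, x, order = 1, Ts = 12)$model
#' @export
fitDiscrete <- function(R, X, order = 2, Ts = 12) {
  if (!(order %in% 1:3)) stop("'order' must be 1, 2 or 3")
  N <- length(R)
  if (length(X) != N) stop("'R' and 'X' must have the same length")
  if (N <= 3 * (order + 1))
    stop("series too short: need length > 3 * (order + 1)")
  if (any(!is.finite(R)) || any(!is.finite(X)))
    stop("series must be finite")
  rows <- (order + 1):N
  nSamples <- length(rows)

  if (all(R == 0)) {
    ## degenerate but well-defined: the zero model reproduces R exactly
    return(list(model = DiscreteARX(a = numeric(order) * 0,
                                    b = numeric(order + 1) * 0, Ts = Ts),
                residualVariance = 0, rSquared = 1,
                nSamples = as.integer(nSamples)))
  }

  regR <- sapply(seq_len(order), function(i) R[rows - i])
  regX <- sapply(0:order, function(j) X[rows - j])
  Z <- cbind(regR, regX)
  y <- R[rows]
  ls <- stats::lm.fit(Z, y)
  theta <- ls$coefficients
  resid <- ls$residuals
  if (ls$rank < ncol(Z)) {
    ## exact collinearity: harmless when the pivoted solution still
    ## reproduces R (overparameterized noise-free data); otherwise the
    ## model is genuinely unidentifiable (e.g. constant input)
    if (sum(resid^2) > 1e-16 * sum(y^2))
      stop(paste("regressor matrix is rank deficient (e.g. constant",
                 "input); the model is not identifiable from these",
                 "series"))
    theta[is.na(theta)] <- 0
  }
  dfree <- nSamples - ncol(Z)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  list(model = DiscreteARX(a = theta[seq_len(order)],
                           b = theta[order + 1:(order + 1)], Ts = Ts),
       residualVariance = rss / max(dfree, 1),
       rSquared = if (tss > 0) 1 - rss / tss else 1,
       nSamples = as.integer(nSamples))
}

#' Identify a continuous sensor model from plate series
#'
#' The complete identification path behind the per-construct parameter
#' tables: fit the bilinear-discretized model by lagged least squares
#' ([fitDiscrete()]), then map the coefficients back to a continuous gain
#' and time constants ([continuousFromDiscrete()]). Continuous parameters
#' are reported only when the fitted poles are real and stable; otherwise
#' the validity flags say why they are absent.
#'
#' @inheritParams fitDiscrete
#' @return A [SensorFit-class].
#' @examples
#' m <- TransferModel(K = 250.84, tauP = c(290.11, 12.69), tauZ = 5)
#' tm <- seq(0, by = 12, length.out = 240)
#' x <- logisticGrowth(GrowthParams(X0 = 0.05, Xmax = 1.2, mu = 0.01,
#'                                  lag = 0), tm)
#' r <- simulateDiscreteARX(bilinearDiscretize(m, 12), x)
#' identifySensor(r, x, order = 2, Ts = 12)
#' @export
identifySensor <- function(R, X, order = 2, Ts = 12) {
  fit <- fitDiscrete(R, X, order = order, Ts = Ts)
  inv <- continuousFromDiscrete(fit$model)
  new("SensorFit", discrete = fit$model, continuous = inv$continuous,
      residualVariance = fit$residualVariance, rSquared = fit$rSquared,
      nSamples = fit$nSamples, flags = inv$flags)
}

#' Fit all three model orders and compare
#'
#' Fits orders 1--3 to the same series. The model classes are nested, so
#' in-sample residual variance is non-increasing with order; higher-order
#' fits that come back unstable or with complex poles are recorded in the
#' per-order flags, not raised (on real screens the third-order model is
#' not always fittable).
#'
#' @inheritParams fitDiscrete
#' @return A list of three [SensorFit-class] objects named
#'   \code{order1..order3}; per-order fit errors are stored as a
#'   \code{try-error}.
#' @export
compareOrders <- function(R, X, Ts = 12) {
  out <- lapply(1:3, function(k) {
    try(identifySensor(R, X, order = k, Ts = Ts), silent = TRUE)
  })
  names(out) <- paste0("order", 1:3)
  out
}

#' Identify every well of a plate run
#'
#' Applies [identifySensor()] to each well of a [PlateTimeSeries-class]
#' and assembles the machine-readable parameter table: one row per well
#' with condition metadata, recovered gain and time constants, and fit
#' diagnostics. Wells whose fit fails (or whose poles are complex or
#' unstable) keep their diagnostics with NA parameters.
#'
#' @param plate a [PlateTimeSeries-class].
#' @param order model order (default 2, the reference model).
#' @param Ts sampling period; defaults to the plate's grid spacing.
#' @return data.frame with columns well_id, construct, iptg_mM,
#'   arabinose_pct, substrate, replicate, order, K, tau_z, tau_1..tau_3,
#'   r_squared, residual_variance, stable, real_poles, positive_gain.
#' @export
identifyPlate <- function(plate, order = 2, Ts = samplingPeriod(plate)) {
  stopifnot(is(plate, "PlateTimeSeries"))
  wells <- wellInfo(plate)
  od <- odMatrix(plate)
  rfp <- rfpMatrix(plate)
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    base <- data.frame(wells[i, .wellColumns, drop = FALSE],
                       order = as.integer(order), K = NA_real_,
                       tau_z = NA_real_, tau_1 = NA_real_,
                       tau_2 = NA_real_, tau_3 = NA_real_,
                       r_squared = NA_real_, residual_variance = NA_real_,
                       stable = NA, real_poles = NA, positive_gain = NA,
                       row.names = NULL)
    fit <- try(identifySensor(rfp[, i], od[, i], order = order, Ts = Ts),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(base)
    base$r_squared <- fit@rSquared
    base$residual_variance <- fit@residualVariance
    base$stable <- fit@flags[["stable"]]
    base$real_poles <- fit@flags[["realPoles"]]
    base$positive_gain <- fit@flags[["positiveGain"]]
    if (!is.null(fit@continuous)) {
      base$K <- fit@continuous@K
      base$tau_z <- fit@continuous@tauZ
      tp <- fit@continuous@tauP
      base$tau_1 <- tp[1]
      if (length(tp) > 1) base$tau_2 <- tp[2]
      if (length(tp) > 2) base$tau_3 <- tp[3]
    }
    base
  })
  do.call(rbind, rows)
}
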