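#' DC gain of a linear model
#'
#' Value of the transfer function at zero frequency (s = 0 for continuous
#' models, z = 1 for discrete models). For every model order this equals
#' the gain K, since all (1 + tau s) factors are 1 at s = 0; the bilinear
#' transform maps s = 0 to z = 1 and so preserves it exactly.
#'
#' @param object a [TransferModel-class] or [DiscreteARX-class].
#' @return The gain as a single number.
#' @examples
#' dcGain(TransferModel(K = 250.84, tauP = c(290.11, 12.69), tauZ = 5))
#' @export
setGeneric("dcGain", function(object) standardGeneric("dcGain"))

#' @rdname dcGain
#' @export
setMethod("dcGain", "TransferModel", function(object) object@K)

#' @rdname dcGain
#' @export
setMethod("dcGain", "DiscreteARX", function(object) {
  sum(object@b) / (1 - sum(object@a))
})

#' Stability of a model
#'
#' A discrete ARX model is stable iff all roots of its autoregressive
#' polynomial lie strictly inside the unit circle; a continuous transfer
#' model with positive time constants is always stable.
#'
#' @param object a [DiscreteARX-class] or [TransferModel-class].
#' @return Logical scalar.
#' @export
setGeneric("isStable", function(object) standardGeneric("isStable"))

#' @rdname isStable
#' @export
setMethod("isStable", "DiscreteARX", function(object) {
  all(Mod(arRoots(object)) < 1)
})

#' @rdname isStable
#' @export
setMethod("isStable", "TransferModel", function(object) all(object@tauP > 0))

## roots of z^n - a1 z^(n-1) - ... - an (internal); polyroot estimates
## are polished by two Newton steps, which matters for clustered poles
arRoots <- function(object) {
  polishRoots(rev(c(1, -object@a)))
}

## asc: coefficients in ascending powers, as polyroot() takes them
polishRoots <- function(asc) {
  r <- polyroot(asc)
  if (!length(r)) return(r)
  dasc <- asc[-1] * seq_along(asc[-1])
  evalp <- function(cf, z) {
    acc <- 0 + 0i
    for (c0 in rev(cf)) acc <- acc * z + c0
    acc
  }
  for (i in 1:2) {
    dp <- evalp(dasc, r)
    step <- ifelse(Mod(dp) > 0, evalp(asc, r) / dp, 0)
    r <- r - step
  }
  r
}

## roots of b0 z^n + ... + bn (internal)
inputRoots <- function(object) {
  b <- object@b
  b <- b / max(abs(b), .Machine$double.xmin)
  if (all(abs(b[-1]) == 0)) return(complex(0))
  polishRoots(rev(b))
}

#' Time grid accessors
#'
#' @param object a [PlateTimeSeries-class].
#' @return \code{timeGrid}: numeric vector of measurement times (min);
#'   \code{samplingPeriod}: the grid spacing Ts (min).
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))

#' @rdname timeGrid
#' @export
setMethod("timeGrid", "PlateTimeSeries", function(object) {
  SummarizedExperiment::rowData(object)$time_min
})

#' @rdname timeGrid
#' @export
setGeneric("samplingPeriod",
           function(object) standardGeneric("samplingPeriod"))

#' @rdname timeGrid
#' @export
setMethod("samplingPeriod", "PlateTimeSeries", function(object) {
  tg <- timeGrid(object)
  if (length(tg) < 2) stop("time grid has fewer than two points")
  tg[2] - tg[1]
})

#' Assay and metadata accessors for plate runs
#'
#' @param object a [PlateTimeSeries-class].
#' @return \code{odMatrix} and \code{rfpMatrix}: time x wells matrices;
#'   \code{wellInfo}: per-well condition metadata as a data.frame.
#' @export
setGeneric("odMatrix", function(object) standardGeneric("odMatrix"))

#' @rdname odMatrix
#' @export
setMethod("odMatrix", "PlateTimeSeries", function(object) {
  SummarizedExperiment::assay(object, "od")
})

#' @rdname odMatrix
#' @export
setGeneric("rfpMatrix", function(object) standardGeneric("rfpMatrix"))

#' @rdname odMatrix
#' @export
setMethod("rfpMatrix", "PlateTimeSeries", function(object) {
  SummarizedExperiment::assay(object, "rfp")
})

#' @rdname odMatrix
#' @export
setGeneric("wellInfo", function(object) standardGeneric("wellInfo"))

#' @rdname odMatrix
#' @export
setMethod("wellInfo", "PlateTimeSeries", function(object) {
  as.data.frame(SummarizedExperiment::colData(object))
})

#' Dissociation constant of the sensor repressor
#'
#' @param object a [SensorParams-class].
#' @return Kd = kr/kf (uM).
#' @export
setGeneric("kdConstant", function(object) standardGeneric("kdConstant"))

#' @rdname kdConstant
#' @export
setMethod("kdConstant", "SensorParams", function(object) {
  object@kr / object@kf
})

setMethod("show", "GrowthParams", function(object) {
  cat("GrowthParams: X0 =", object@X0, "Xmax =", object@Xmax,
      "mu =", object@mu, "/min, lag =", object@lag, "min\n")
})

setMethod("show", "SensorParams", function(object) {
  cat("SensorParams (uM, min):\n")
  cat("  production vm =", object@vm, " growth use vg =", object@vg,
      " decay gammaM =", object@gammaM, "\n")
  cat("  binding kf =", object@kf, " kr =", object@kr,
      " (Kd =", kdConstant(object), "uM), FapR =", object@fapR, "\n")
  cat("  reporter kappa =", object@kappa, " gammaR =", object@gammaR, "\n")
})

setMethod("show", "InductionMap", function(object) {
  cat("InductionMap (Hill): basal =", object@basal, "+", object@vmax,
      "* I^", object@n, "/ (", object@Kh, "^", object@n, "+ I^",
      object@n, ")\n")
})

setMethod("show", "TransferModel", function(object) {
  cat("TransferModel order", object@order, ": K =", object@K,
      " tauZ =", object@tauZ, "min, tauP =",
      paste(signif(object@tauP, 6), collapse = ", "), "min\n")
})

setMethod("show", "DiscreteARX", function(object) {
  cat("DiscreteARX (Ts =", object@Ts, "min):\n")
  cat("  a =", paste(signif(object@a, 6), collapse = ", "), "\n")
  cat("  b =", paste(signif(object@b, 6), collapse = ", "), "\n")
  cat("  DC gain =", signif(dcGain(object), 6),
      if (isStable(object)) " (stable)\n" else " (UNSTABLE)\n")
})

setMethod("show", "SensorFit", function(object) {
  cat("SensorFit on", object@nSamples, "samples: R^2 =",
      signif(object@rSquared, 4), " resid var =",
      signif(object@residualVariance, 4), "\n")
  cat("  flags:", paste(names(object@flags), object@flags, sep = "=",
                        collapse = " "), "\n")
  if (!is.null(object@continuous)) {
    cat("  ")
    show(object@continuous)
  } else cat("  continuous parameters unavailable (see flags)\n")
})

setMethod("show", "PlateTimeSeries", function(object) {
  callNextMethod()
  tg <- timeGrid(object)
  cat("plate run:", ncol(object), "wells x", length(tg),
      "time points, Ts =",
      if (length(tg) > 1) tg[2] - tg[1] else NA, "min\n")
})
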