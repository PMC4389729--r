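## polynomial product, coefficients in descending powers (internal)
polyMul <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    idx <- i + seq_along(q) - 1
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Bilinear (Tustin) discretization of a transfer model
#'
#' Substitutes \eqn{s = (2/T_s)(z - 1)/(z + 1)} into
#' \eqn{K (1 - \tau_z s) / \prod_i (1 + \tau_{p,i} s)} and expands to
#' monic-denominator difference-equation coefficients. Because the
#' substitution maps s = 0 to z = 1, the DC gain of the result equals K
#' exactly, and stability is preserved in both directions (left-half-plane
#' poles map inside the unit circle).
#'
#' @param model a [TransferModel-class].
#' @param Ts sampling period (min); a warning is issued when
#'   Ts >= 2 * min(tauP), where the frequency warping of the transform
#'   degrades the pole mapping.
#' @return A [DiscreteARX-class] with \code{order} autoregressive and
#'   \code{order + 1} input coefficients.
#' @seealso [continuousFromDiscrete()] for the inverse mapping.
#' @examples
#' bilinearDiscretize(TransferModel(K = 1, tauP = 1), Ts = 2)
#' # a = 0, b = c(0.5, 0.5)
#' @export
bilinearDiscretize <- function(model, Ts) {
  stopifnot(is(model, "TransferModel"))
  validObject(model)
  if (length(Ts) != 1L || !is.finite(Ts) || Ts <= 0)
    stop("'Ts' must be a single number > 0")
  if (Ts >= 2 * min(model@tauP))
    warning(sprintf(
      "Ts = %g is not below 2 * min(tauP) = %g; pole mapping is degraded",
      Ts, 2 * min(model@tauP)))
  cc <- 2 / Ts
  den <- Reduce(polyMul,
                lapply(model@tauP, function(tp) c(1 + tp * cc, 1 - tp * cc)))
  num <- c(1 - model@tauZ * cc, 1 + model@tauZ * cc)
  if (model@order > 1L)
    for (i in seq_len(model@order - 1L)) num <- polyMul(num, c(1, 1))
  num <- model@K * num
  a <- -den[-1] / den[1]
  b <- num / den[1]
  ## DC-normalize: the map preserves the gain analytically, but the
  ## expanded coefficients cancel strongly at z = 1 when tau >> Ts, so
  ## rounding is compensated to keep sum(b)/(1 - sum(a)) = K exactly
  b <- b * (model@K * (1 - sum(a)) / sum(b))
  DiscreteARX(a = a, b = b, Ts = Ts)
}

#' Forward-simulate a discrete ARX model
#'
#' Iterates \eqn{R[k] = \sum_i a_i R[k-i] + \sum_j b_j X[k-j]} with zero
#' initial conditions (samples before the series start are taken as 0).
#'
#' @param model a [DiscreteARX-class].
#' @param input numeric input series X, length >= model order.
#' @return Numeric output series of the same length. When the model is
#'   unstable (an AR root on or outside the unit circle) the result
#'   carries attribute \code{unstable = TRUE} and a warning is raised; the
#'   simulation still runs.
#' @examples
#' m <- DiscreteARX(a = 0.5, b = c(1, 0), Ts = 12)
#' simulateDiscreteARX(m, c(1, 0, 0, 0))  # geometric impulse response
#' @export
simulateDiscreteARX <- function(model, input) {
  stopifnot(is(model, "DiscreteARX"))
  validObject(model)
  n <- length(model@a)
  if (length(input) < n)
    stop("input series must be at least as long as the model order")
  unstable <- !isStable(model)
  if (unstable)
    warning("ARX model is unstable (AR root on/outside the unit circle)")
  N <- length(input)
  out <- numeric(N)
  a <- model@a
  b <- model@b
  for (k in seq_len(N)) {
    acc <- 0
    for (i in seq_len(n)) if (k - i >= 1) acc <- acc + a[i] * out[k - i]
    for (j in 0:n) if (k - j >= 1) acc <- acc + b[j + 1] * input[k - j]
    out[k] <- acc
  }
  if (unstable) attr(out, "unstable") <- TRUE
  out
}

#' Map a discrete ARX model back to continuous parameters
#'
#' Inverts the bilinear substitution: each root \eqn{z_i} of the
#' autoregressive polynomial is mapped to
#' \eqn{s_i = (2/T_s)(z_i - 1)/(z_i + 1)} and \eqn{\tau_{p,i} = -1/s_i}
#' (reported descending, slow constant first). The gain is the DC gain.
#' The derivative constant tauZ comes from the numerator root that does
#' not sit at z = -1 (the image of s = infinity, where the (z+1) factors
#' of the expansion accumulate); surplus numerator roots beyond one are
#' flagged as unmodeled dynamics rather than mapped.
#'
#' @param model a [DiscreteARX-class] of order 1--3.
#' @return A list with elements \code{continuous} (a
#'   [TransferModel-class], or NULL when the poles are complex or
#'   unstable) and \code{flags} (named logical: \code{stable},
#'   \code{realPoles}, \code{positiveGain}, \code{extraZeros}).
#' @examples
#' continuousFromDiscrete(DiscreteARX(a = 0, b = c(0.5, 0.5), Ts = 2))
#' # K = 1, tauP = 1
#' @export
continuousFromDiscrete <- function(model) {
  stopifnot(is(model, "DiscreteARX"))
  validObject(model)
  zr <- arRoots(model)
  if (any(Mod(zr + 1) < 1e-10))
    stop("AR pole at z = -1 (Nyquist); the bilinear map is singular there")
  stable <- all(Mod(zr) < 1)
  realPoles <- all(abs(Im(zr)) <= 1e-8 * (1 + Mod(zr)))
  K <- dcGain(model)
  flags <- c(stable = stable, realPoles = realPoles,
             positiveGain = K > 0, extraZeros = FALSE)

  ## numerator roots: separate the zero image from the (z + 1) cluster
  nr <- inputRoots(model)
  nr <- nr[Mod(nr + 1) > 1e-6]
  tauZ <- 0
  if (length(nr)) {
    sZeros <- (2 / model@Ts) * (nr - 1) / (nr + 1)
    keep <- order(abs(Im(sZeros)))[1]
    sz <- sZeros[keep]
    if (abs(Im(sz)) <= 1e-8 * (1 + Mod(sz)) && abs(Re(sz)) > 0)
      tauZ <- 1 / Re(sz)
    if (length(nr) > 1L) flags["extraZeros"] <- TRUE
  }

  if (!(stable && realPoles))
    return(list(continuous = NULL, flags = flags))

  s <- (2 / model@Ts) * (Re(zr) - 1) / (Re(zr) + 1)
  tauP <- sort(-1 / s, decreasing = TRUE)
  cont <- new("TransferModel", order = length(tauP), K = K,
              tauZ = max(tauZ, 0), tauP = tauP)
  list(continuous = cont, flags = flags)
}
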