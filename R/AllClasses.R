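#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approxfun cor.test rnorm sd t.test var
#' @importFrom utils read.csv write.csv
NULL

#' Logistic growth parameters
#'
#' Parameters of a logistic (Verhulst) biomass curve with an optional lag
#' phase, used as the culture-growth input of the biosensor cascade. Units
#' are OD600 for biomass and minutes for time.
#'
#' @slot X0 initial biomass (OD600 units, must satisfy 0 < X0 < Xmax).
#' @slot Xmax carrying capacity (OD600 units).
#' @slot mu specific growth rate (1/min, > 0).
#' @slot lag lag-phase duration (min, >= 0); biomass stays at \code{X0}
#'   until \code{lag}.
#'
#' @seealso [GrowthParams()], [logisticGrowth()]
#' @export
setClass("GrowthParams",
  slots = c(X0 = "numeric", Xmax = "numeric", mu = "numeric", lag = "numeric"))

setValidity("GrowthParams", function(object) {
  msg <- character()
  for (s in c("X0", "Xmax", "mu", "lag"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (!length(msg)) {
    if (object@X0 <= 0) msg <- c(msg, "X0 must be > 0")
    if (object@Xmax <= object@X0) msg <- c(msg, "Xmax must exceed X0")
    if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
    if (object@lag < 0) msg <- c(msg, "lag must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct logistic growth parameters
#'
#' Defaults emulate an overnight culture diluted 20-fold into minimal
#' medium: start near OD 0.05, plateau near OD 1.2, a doubling time of
#' about 70 min and a one-hour lag.
#'
#' @param X0 initial biomass (OD600).
#' @param Xmax carrying capacity (OD600).
#' @param mu specific growth rate (1/min).
#' @param lag lag duration (min).
#' @return A [GrowthParams-class] object.
#' @examples
#' gp <- GrowthParams(X0 = 0.05, Xmax = 1.2, mu = 0.01, lag = 0)
#' @export
GrowthParams <- function(X0 = 0.05, Xmax = 1.2, mu = 0.01, lag = 60) {
  new("GrowthParams", X0 = X0, Xmax = Xmax, mu = mu, lag = lag)
}

#' Mechanistic constants of the biosensor cascade
#'
#' Rate constants of the three-stage sensor model: a malonyl-CoA balance
#' driven by biomass, reversible binding of malonyl-CoA to the FapR
#' repressor, and expression of the RFP reporter proportional to the bound
#' complex. Concentrations are in uM, time in minutes, fluorescence in
#' arbitrary units.
#'
#' @slot vm malonyl-CoA production rate (uM/(OD*min)); construct- and
#'   induction-dependent.
#' @slot vg malonyl-CoA consumption per unit of biomass formed (uM/OD);
#'   multiplies dX/dt in the balance. Default 0 (term switchable).
#' @slot gammaM malonyl-CoA decay/turnover rate (1/min).
#' @slot kf FapR--malonyl-CoA association rate (1/(uM*min)).
#' @slot kr complex dissociation rate (1/min); Kd = kr/kf defaults to
#'   2.4 uM, the reported FapR dissociation constant.
#' @slot fapR free FapR concentration (uM), held constant at the level set
#'   by arabinose induction.
#' @slot kappa promoter-strength constant coupling complex concentration to
#'   fluorescence production (a.u./(uM*min)).
#' @slot gammaR reporter decay rate (1/min); for a stable RFP this is
#'   dominated by growth dilution.
#'
#' @seealso [SensorParams()], [simulateSensorCascade()], [steadyStateGain()]
#' @export
setClass("SensorParams",
  slots = c(vm = "numeric", vg = "numeric", gammaM = "numeric",
            kf = "numeric", kr = "numeric", fapR = "numeric",
            kappa = "numeric", gammaR = "numeric"))

setValidity("SensorParams", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    else if (v < 0)
      msg <- c(msg, sprintf("'%s' must be >= 0", s))
  }
  if (!length(msg) && object@kf <= 0)
    msg <- c(msg, "kf must be > 0 so that Kd = kr/kf is defined")
  if (length(msg)) msg else TRUE
})

#' Construct sensor cascade parameters
#'
#' Defaults give a slow reporter pole (1/gammaR ~ 290 min), an intermediate
#' metabolite pole (1/gammaM ~ 13 min) and fast binding (1/kr < 1 min), so
#' the cascade behaves like the second-order filter used for
#' identification; Kd = kr/kf = 2.4 uM.
#'
#' @param vm,vg,gammaM,kf,kr,fapR,kappa,gammaR see [SensorParams-class].
#' @return A [SensorParams-class] object.
#' @examples
#' sp <- SensorParams(vm = 0.1)
#' kdConstant(sp)
#' @export
SensorParams <- function(vm = 0.1, vg = 0, gammaM = 0.077, kf = 1,
                         kr = 2.4, fapR = 1, kappa = 2,
                         gammaR = 1 / 290) {
  new("SensorParams", vm = vm, vg = vg, gammaM = gammaM, kf = kf, kr = kr,
      fapR = fapR, kappa = kappa, gammaR = gammaR)
}

#' Hill-type induction map
#'
#' Monotone map from an inducer concentration to a model rate or
#' concentration, used to translate IPTG doses into the malonyl-CoA
#' production rate vm and arabinose doses into the FapR level.
#'
#' @slot basal output at zero inducer.
#' @slot vmax saturating increment above basal.
#' @slot Kh half-saturation inducer concentration.
#' @slot n Hill exponent (>= 1).
#'
#' @seealso [InductionMap()], [inductionToRate()]
#' @export
setClass("InductionMap",
  slots = c(basal = "numeric", vmax = "numeric", Kh = "numeric",
            n = "numeric"))

setValidity("InductionMap", function(object) {
  msg <- character()
  for (s in slotNames(object))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (!length(msg)) {
    if (object@basal < 0 || object@vmax < 0)
      msg <- c(msg, "basal and vmax must be >= 0")
    if (object@Kh <= 0) msg <- c(msg, "Kh must be > 0")
    if (object@n < 1) msg <- c(msg, "n must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Hill induction map
#'
#' Defaults place the half-saturation dose at 0.3 mM, inside the usual
#' IPTG screening series (0.01--10 mM).
#'
#' @param basal,vmax,Kh,n see [InductionMap-class].
#' @return An [InductionMap-class] object.
#' @examples
#' m <- InductionMap(basal = 0.005, vmax = 0.1, Kh = 0.3)
#' inductionToRate(c(0, 0.3, 100), m)
#' @export
InductionMap <- function(basal = 0.005, vmax = 0.1, Kh = 0.3, n = 1) {
  new("InductionMap", basal = basal, vmax = vmax, Kh = Kh, n = n)
}

#' Approximate linear filter model of the sensor
#'
#' Continuous transfer model between biomass X(t) and fluorescence R(t):
#' a gain K, one derivative (zero) time constant tauZ and one to three
#' integral (pole) time constants tauP, i.e.
#' \deqn{R(s)/X(s) = K (1 - \tau_z s) / \prod_i (1 + \tau_{p,i} s).}
#'
#' @slot order number of poles (1, 2 or 3).
#' @slot K gain (fluorescence per OD unit).
#' @slot tauZ derivative time constant (min, >= 0).
#' @slot tauP integral time constants (min), sorted descending so tauP[1]
#'   is the slow constant.
#'
#' @seealso [TransferModel()], [simulateTransferModel()], [dcGain()]
#' @export
setClass("TransferModel",
  slots = c(order = "integer", K = "numeric", tauZ = "numeric",
            tauP = "numeric"))

setValidity("TransferModel", function(object) {
  msg <- character()
  if (!(object@order %in% 1:3)) msg <- c(msg, "order must be 1, 2 or 3")
  if (length(object@K) != 1L || !is.finite(object@K))
    msg <- c(msg, "K must be a single finite number")
  if (length(object@tauZ) != 1L || !is.finite(object@tauZ) ||
      object@tauZ < 0)
    msg <- c(msg, "tauZ must be a single number >= 0")
  if (length(object@tauP) != object@order)
    msg <- c(msg, "length(tauP) must equal order")
  else if (any(!is.finite(object@tauP)) || any(object@tauP <= 0))
    msg <- c(msg, "all tauP must be finite and > 0")
  else if (is.unsorted(rev(object@tauP)))
    msg <- c(msg, "tauP must be sorted descending (slow constant first)")
  if (length(msg)) msg else TRUE
})

#' Construct a transfer model
#'
#' @param K gain.
#' @param tauP integral time constants (min); sorted descending
#'   internally; their number sets the model order.
#' @param tauZ derivative time constant (min).
#' @return A [TransferModel-class] object.
#' @examples
#' m2 <- TransferModel(K = 250.84, tauP = c(290.11, 12.69), tauZ = 5)
#' dcGain(m2)
#' @export
TransferModel <- function(K, tauP, tauZ = 0) {
  new("TransferModel", order = length(tauP), K = K, tauZ = tauZ,
      tauP = sort(tauP, decreasing = TRUE))
}

#' Discrete ARX model at sampling period Ts
#'
#' Difference-equation form of a bilinear-discretized transfer model:
#' \deqn{R[k] = \sum_{i=1}^{order} a_i R[k-i] + \sum_{j=0}^{order} b_j X[k-j].}
#'
#' @slot a autoregressive coefficients (length = order).
#' @slot b input coefficients (length = order + 1).
#' @slot Ts sampling period (min, > 0).
#'
#' @seealso [DiscreteARX()], [bilinearDiscretize()], [simulateDiscreteARX()]
#' @export
setClass("DiscreteARX",
  slots = c(a = "numeric", b = "numeric", Ts = "numeric"))

setValidity("DiscreteARX", function(object) {
  msg <- character()
  if (length(object@a) < 1L || length(object@a) > 3L ||
      any(!is.finite(object@a)))
    msg <- c(msg, "a must hold 1-3 finite coefficients")
  if (length(object@b) != length(object@a) + 1L ||
      any(!is.finite(object@b)))
    msg <- c(msg, "b must hold order + 1 finite coefficients")
  if (length(object@Ts) != 1L || !is.finite(object@Ts) || object@Ts <= 0)
    msg <- c(msg, "Ts must be a single number > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a discrete ARX model
#'
#' @param a autoregressive coefficients.
#' @param b input coefficients (one more than \code{a}).
#' @param Ts sampling period (min); defaults to the 12-min plate-reader
#'   cycle.
#' @return A [DiscreteARX-class] object.
#' @examples
#' m <- DiscreteARX(a = 0, b = c(0.5, 0.5), Ts = 2)
#' dcGain(m)
#' @export
DiscreteARX <- function(a, b, Ts = 12) {
  new("DiscreteARX", a = as.numeric(a), b = as.numeric(b), Ts = Ts)
}

setClassUnion("TransferModelOrNULL", c("TransferModel", "NULL"))

#' Identification result for one fluorescence/biomass series
#'
#' Bundles the fitted discrete ARX model, the continuous parameters mapped
#' back through the inverse bilinear transform (absent when the fitted
#' poles are complex or unstable), regression diagnostics and validity
#' flags.
#'
#' @slot discrete fitted [DiscreteARX-class] model.
#' @slot continuous [TransferModel-class] with recovered K, tauZ, tauP, or
#'   NULL when the discrete poles are complex or unstable (the validity
#'   flags say which).
#' @slot residualVariance residual variance of the lag regression
#'   (df-adjusted).
#' @slot rSquared in-sample R-squared of R[k].
#' @slot nSamples number of regression rows used.
#' @slot flags named logical vector: \code{stable}, \code{realPoles},
#'   \code{positiveGain}, and \code{extraZeros} marking surplus numerator
#'   roots treated as unmodeled dynamics.
#'
#' @seealso [identifySensor()], [fitDiscrete()]
#' @export
setClass("SensorFit",
  slots = c(discrete = "DiscreteARX", continuous = "TransferModelOrNULL",
            residualVariance = "numeric", rSquared = "numeric",
            nSamples = "integer", flags = "logical"))

setValidity("SensorFit", function(object) {
  msg <- character()
  need <- c("stable", "realPoles", "positiveGain", "extraZeros")
  if (!all(need %in% names(object@flags)))
    msg <- c(msg, paste("flags must contain", paste(need, collapse = ", ")))
  else if (!is.null(object@continuous) &&
           !(object@flags[["stable"]] && object@flags[["realPoles"]]))
    msg <- c(msg,
      "continuous parameters may be present only for stable real poles")
  if (length(msg)) msg else TRUE
})

#' Plate-reader time series container
#'
#' A \linkS4class{SummarizedExperiment} holding one kinetic microplate run:
#' two assays (\code{od} and \code{rfp}, time points x wells) on a shared
#' uniform time grid, with per-well condition metadata (construct, IPTG,
#' arabinose, substrate supplementation, replicate) in \code{colData} and
#' the time grid in \code{rowData}.
#'
#' @seealso [PlateTimeSeries()], [generatePlate()], [readPlateCsv()]
#' @export
setClass("PlateTimeSeries", contains = "SummarizedExperiment")

.wellColumns <- c("well_id", "construct", "iptg_mM", "arabinose_pct",
                  "substrate", "replicate")

setValidity("PlateTimeSeries", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("od", "rfp") %in% an))
    msg <- c(msg, "assays 'od' and 'rfp' are required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"time_min" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'time_min'")
  else {
    tg <- rd$time_min
    if (length(tg) > 1) {
      dt <- diff(tg)
      if (any(dt <= 0) || diff(range(dt)) > 1e-8 * mean(dt))
        msg <- c(msg, "time grid must be uniform and increasing")
    }
  }
  miss <- setdiff(.wellColumns, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData lacks columns:", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (any(SummarizedExperiment::assay(object, "od") < 0, na.rm = TRUE))
      msg <- c(msg, "OD values must be >= 0")
    if (any(SummarizedExperiment::assay(object, "rfp") < 0, na.rm = TRUE))
      msg <- c(msg, "fluorescence values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlateTimeSeries
#'
#' @param time numeric vector of measurement times (min), uniformly spaced.
#' @param od,rfp numeric matrices, time points x wells.
#' @param wellData data.frame with one row per well and columns
#'   \code{well_id}, \code{construct}, \code{iptg_mM}, \code{arabinose_pct},
#'   \code{substrate}, \code{replicate}.
#' @param metadata optional list stored in the object metadata (the plate
#'   generator records its parameters and seed here).
#' @return A [PlateTimeSeries-class] object.
#' @examples
#' tm <- seq(0, 120, by = 12)
#' od <- matrix(seq(0.05, 0.6, length.out = length(tm)), ncol = 1)
#' wells <- data.frame(well_id = "A1", construct = "ctrl", iptg_mM = 0,
#'                     arabinose_pct = 0.01, substrate = FALSE,
#'                     replicate = 1L)
#' p <- PlateTimeSeries(tm, od, od * 100, wells)
#' samplingPeriod(p)
#' @export
PlateTimeSeries <- function(time, od, rfp, wellData, metadata = list()) {
  od <- as.matrix(od)
  rfp <- as.matrix(rfp)
  if (nrow(od) != length(time) || !all(dim(od) == dim(rfp)))
    stop("'od' and 'rfp' must be time x wells matrices on 'time'")
  if (nrow(wellData) != ncol(od))
    stop("'wellData' must have one row per well")
  colnames(od) <- colnames(rfp) <- wellData$well_id
  new("PlateTimeSeries", SummarizedExperiment::SummarizedExperiment(
    assays = list(od = od, rfp = rfp),
    rowData = S4Vectors::DataFrame(time_min = as.numeric(time)),
    colData = S4Vectors::DataFrame(wellData, row.names = wellData$well_id),
    metadata = metadata))
}
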