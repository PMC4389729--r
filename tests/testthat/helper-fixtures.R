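## Per-construct gain and integral time constants of the reference
## second-order sensor model (fluorescence/OD and minutes).
constructParams <- function() {
  data.frame(
    construct = c("matCmatB", "mmsA", "cagg", "acc", "matCatoDA"),
    K = c(250.84, 300.53, 362.82, 320.20, 321.12),
    tau1 = c(290.11, 288.31, 525.90, 417.92, 156.95),
    tau2 = c(12.69, 15.67, 17.39, 11.49, 11.14))
}

relErr <- function(x, ref) abs(x - ref) / abs(ref)

## logistic biomass input on the 12-min grid used throughout
logisticInput <- function(n = 240, Ts = 12, mu = 0.01, lag = 0) {
  tm <- seq(0, by = Ts, length.out = n)
  list(time = tm,
       X = logisticGrowth(GrowthParams(X0 = 0.05, Xmax = 1.2, mu = mu,
                                       lag = lag), tm))
}

## random stable transfer model with well-separated dynamics
randomTransferModel <- function(order = 2) {
  K <- runif(1, 50, 500)
  tauZ <- runif(1, 0, 20)
  tauP <- sort(runif(order, 25, 600), decreasing = TRUE)
  new("TransferModel", order = as.integer(order), K = K, tauZ = tauZ,
      tauP = tauP)
}
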