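test_that("OD-anchored readout interpolates the first upward crossing", {
  ## midpoint interpolation between samples straddling the threshold
  r <- readoutAtOD(c(0.5, 0.7), c(100, 200), c(0, 12))
  expect_equal(r$fluorescence, 150)
  expect_equal(r$crossingTime, 6)
  ## on-grid crossing returns that sample
  r2 <- readoutAtOD(c(0.4, 0.6, 0.8), c(10, 20, 30), c(0, 12, 24))
  expect_equal(r2$fluorescence, 20)
  expect_equal(r2$crossingTime, 12)
  ## later crossings after a dip are ignored
  od <- c(0.4, 0.65, 0.55, 0.7)
  r3 <- readoutAtOD(od, c(0, 100, 200, 300), c(0, 12, 24, 36))
  expect_lt(r3$crossingTime, 12)
  ## no growth
  expect_error(readoutAtOD(c(0.1, 0.2, 0.3), c(1, 2, 3), c(0, 12, 24)),
               "no growth")
  expect_error(readoutAtOD(c(0.7, 0.8), c(1, 2), c(0, 12)),
               "below the threshold")
})

test_that("readout is invariant to grid refinement of piecewise-linear data", {
  tm <- seq(0, 480, by = 12)
  od <- seq(0.1, 1.1, length.out = length(tm))
  rfp <- 50 + 2 * tm
  coarse <- readoutAtOD(od, rfp, tm)
  tm2 <- seq(0, 480, by = 3)
  od2 <- approx(tm, od, tm2)$y
  rfp2 <- approx(tm, rfp, tm2)$y
  fine <- readoutAtOD(od2, rfp2, tm2)
  expect_equal(fine$fluorescence, coarse$fluorescence, tolerance = 1e-12)
  expect_equal(fine$crossingTime, coarse$crossingTime, tolerance = 1e-12)
})

test_that("RFP/OD normalization masks low biomass instead of exploding", {
  od <- c(0, 0.02, 0.5, 1)
  rfp <- 2 * od
  out <- normalizeRfpOd(od, rfp, odFloor = 0.05)
  expect_true(all(is.na(out[1:2])))
  expect_equal(out[3:4], c(2, 2))
})

test_that("reporter lag produces the early dip in RFP/OD", {
  tm <- seq(0, 1440, by = 12)
  gp <- GrowthParams(lag = 0)
  X <- logisticGrowth(gp, tm)
  ## nonzero initial reporter (background) decays while growth outpaces
  ## expression, then induction catches up
  out <- simulateSensorCascade(SensorParams(vm = 0.1), gp, tm,
                               init = c(M = 0, C = 0, R = 30))
  ratio <- normalizeRfpOd(X, out$R, odFloor = 0.0)
  expect_lt(min(ratio), ratio[1])
  expect_gt(tail(ratio, 1), min(ratio))
})

test_that("dose-response summarises and is order invariant", {
  dose <- c(0.1, 0.1, 1, 1, 10, 10)
  y <- c(10, 12, 30, 34, 50, 54)
  dr <- doseResponse(y, dose)
  expect_equal(dr$dose, c(0.1, 1, 10))
  expect_equal(dr$mean, c(11, 32, 52))
  expect_equal(dr$n, c(2L, 2L, 2L))
  shuf <- sample(length(y))
  expect_equal(doseResponse(y[shuf], dose[shuf]), dr)
  ## single replicates: raw values, zero dispersion
  dr1 <- doseResponse(c(1, 2), c(0.1, 1))
  expect_equal(dr1$mean, c(1, 2))
  expect_equal(dr1$sd, c(0, 0))
  expect_error(doseResponse(c(1, 2), c(1, 1)), "two inducer")
})

test_that("dose-response on Hill-generated readouts rises monotonically", {
  set.seed(31)
  m <- InductionMap(basal = 10, vmax = 100, Kh = 0.3, n = 1)
  dose <- rep(c(0.01, 0.1, 0.3, 0.6, 1, 10), each = 4)
  y <- inductionToRate(dose, m) * (1 + 0.03 * rnorm(length(dose)))
  dr <- doseResponse(y, dose)
  expect_true(all(diff(dr$mean) > 0))
})

test_that("pearsonR matches the closed-form estimator", {
  expect_equal(pearsonR(1:10, 2 * (1:10) + 1)$r, 1)
  x <- c(-2, -1, 0, 1, 2)
  y <- c(1, -2, 0, 2, -1)  # constructed orthogonal to x
  expect_equal(sum(x * y), 0)
  expect_equal(pearsonR(x, y)$r, 0)
  ## brute-force formula oracle
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  rRef <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearsonR(x, y)
  expect_equal(res$r, rRef, tolerance = 1e-12)
  tRef <- rRef * sqrt(2 / (1 - rRef^2))
  expect_equal(res$pValue, 2 * pt(-abs(tRef), df = 2), tolerance = 1e-12)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("substrate effect test matches a hand-computed Welch test", {
  a <- c(10, 11, 12)
  expect_error(substrateEffectTest(a, 5), "2 replicates")
  same <- substrateEffectTest(a, a + 0.0)
  expect_false(same$significant)
  ## groups far apart: compute Welch statistic and p directly
  b <- a + 10
  res <- substrateEffectTest(b, a)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tRef <- (mean(b) - mean(a)) / se
  dfRef <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$pValue, 2 * pt(-abs(tRef), dfRef), tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$direction, 1)
  ## swapping groups flips direction, keeps p
  sw <- substrateEffectTest(a, b)
  expect_equal(sw$pValue, res$pValue)
  expect_equal(sw$direction, -1)
})

test_that("replicate CV is sd/mean and scale invariant", {
  expect_equal(replicateCV(c(90, 110)), sqrt(200) / 100)
  expect_equal(replicateCV(c(5, 5, 5)), 0)
  v <- c(80, 95, 120)
  expect_equal(replicateCV(7 * v), replicateCV(v))
  expect_error(replicateCV(c(-1, 1)), "positive")
  expect_error(replicateCV(3), "2 replicates")
})

test_that("parameter-induction correlation separates gain from time constants", {
  set.seed(13)
  doses <- rep(c(0.01, 0.1, 0.3, 0.6, 1, 10), each = 4)
  m <- InductionMap(basal = 50, vmax = 300, Kh = 0.3, n = 1)
  mk <- function(K) data.frame(
    iptg_mM = doses, construct = rep(c("A", "B"), length(doses) / 2),
    K = K, tau_1 = 290 * (1 + 0.05 * rnorm(length(doses))),
    tau_2 = 12.7 * (1 + 0.05 * rnorm(length(doses))),
    tau_z = 5 + 0.2 * rnorm(length(doses)))
  ## dose-responsive gain: strong correlation with log dose
  fits <- mk(inductionToRate(doses, m) * (1 + 0.05 * rnorm(length(doses))))
  out <- paramInductionCorrelation(fits)
  rK <- out$correlations$r[out$correlations$parameter == "K"]
  rT <- out$correlations$r[out$correlations$parameter == "tau_1"]
  expect_gt(rK, 0.7)
  expect_lt(abs(rT), 0.3)
  expect_true(all(c("construct", "parameter", "mean", "sd") %in%
                  colnames(out$tauByConstruct)))
  ## constant vm across doses: gain correlation collapses
  fits0 <- mk(200 * (1 + 0.05 * rnorm(length(doses))))
  out0 <- paramInductionCorrelation(fits0)
  expect_lt(abs(out0$correlations$r[out0$correlations$parameter == "K"]),
            0.3)
  expect_error(paramInductionCorrelation(fits[fits$iptg_mM < 0.3, ]),
               "4 induction levels")
})
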