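test_that("noise-free ARX data returns the exact coefficients", {
  inp <- logisticInput(240)
  true <- bilinearDiscretize(TransferModel(K = 300, tauP = c(250, 20),
                                           tauZ = 5), Ts = 12)
  r <- simulateDiscreteARX(true, inp$X)
  fit <- fitDiscrete(r, inp$X, order = 2, Ts = 12)
  expect_lt(max(relErr(fit$model@a, true@a)), 1e-8)
  expect_lt(max(relErr(fit$model@b, true@b)), 1e-8)
  expect_lt(fit$residualVariance, 1e-16)
})

test_that("an all-zero response gives the zero model with zero residual", {
  inp <- logisticInput(60)
  fit <- fitDiscrete(rep(0, 60), inp$X, order = 2, Ts = 12)
  expect_equal(fit$model@a, c(0, 0))
  expect_equal(fit$model@b, c(0, 0, 0))
  expect_equal(fit$residualVariance, 0)
})

test_that("constant input is flagged as unidentifiable", {
  set.seed(5)
  r <- cumsum(rnorm(60))^2
  expect_error(fitDiscrete(r, rep(1, 60), order = 2, Ts = 12),
               "rank deficient")
  expect_error(fitDiscrete(r[1:8], rep(1, 8), order = 2, Ts = 12),
               "too short")
})

test_that("coefficient error vanishes with the measurement noise", {
  inp <- logisticInput(240)
  true <- bilinearDiscretize(TransferModel(K = 300, tauP = c(250, 20),
                                           tauZ = 6), Ts = 12)
  clean <- simulateDiscreteARX(true, inp$X)
  err <- sapply(c(1e-2, 1e-3, 1e-4), function(sig) {
    mean(sapply(1:5, function(s) {
      set.seed(100 + s)
      noisy <- clean * (1 + sig * rnorm(length(clean)))
      f <- fitDiscrete(noisy, inp$X, order = 2, Ts = 12)
      max(abs(c(f$model@a - true@a, f$model@b - true@b)))
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("full identification recovers the per-construct parameter table", {
  inp <- logisticInput(240)
  tbl <- constructParams()
  for (i in seq_len(nrow(tbl))) {
    true <- TransferModel(K = tbl$K[i], tauP = c(tbl$tau1[i], tbl$tau2[i]),
                          tauZ = 5)
    r <- simulateDiscreteARX(bilinearDiscretize(true, 12), inp$X)
    fit <- identifySensor(r, inp$X, order = 2, Ts = 12)
    expect_true(all(fit@flags[c("stable", "realPoles", "positiveGain")]))
    expect_lt(relErr(fit@continuous@K, tbl$K[i]), 1e-6)
    expect_lt(relErr(fit@continuous@tauP[1], tbl$tau1[i]), 1e-6)
    expect_lt(relErr(fit@continuous@tauP[2], tbl$tau2[i]), 1e-6)
  }
})

test_that("model orders are nested: residuals shrink, never grow", {
  inp <- logisticInput(240)
  true2 <- bilinearDiscretize(TransferModel(K = 300, tauP = c(250, 20),
                                            tauZ = 6), Ts = 12)
  clean <- simulateDiscreteARX(true2, inp$X)
  ## noise-free order-2 truth: orders 2 and 3 are exact, order 1 is not
  cmp <- compareOrders(clean, inp$X, Ts = 12)
  rv <- sapply(cmp, function(f) f@residualVariance)
  expect_gt(rv[["order1"]], 1e-6)
  expect_lt(rv[["order2"]], 1e-16)
  expect_lt(rv[["order3"]], 1e-14)
  ## order-1 truth: all three orders reach ~zero residual in sample
  true1 <- bilinearDiscretize(TransferModel(K = 100, tauP = 150, tauZ = 3),
                              Ts = 12)
  clean1 <- simulateDiscreteARX(true1, inp$X)
  rv1 <- sapply(compareOrders(clean1, inp$X, Ts = 12),
                function(f) f@residualVariance)
  expect_true(all(rv1 < 1e-14))
  ## on noisy data the in-sample residual is monotone in order
  set.seed(9)
  noisy <- clean * (1 + 0.02 * rnorm(length(clean)))
  rvN <- sapply(compareOrders(noisy, inp$X, Ts = 12),
                function(f) f@residualVariance)
  expect_true(all(diff(rvN) <= 1e-3 * rvN[1]))
})

test_that("white noise unrelated to the input has near-zero R-squared", {
  inp <- logisticInput(200)
  set.seed(21)
  r2 <- replicate(5, {
    r <- abs(rnorm(200))
    max(sapply(compareOrders(r, inp$X, Ts = 12),
               function(f) f@rSquared))
  })
  expect_lt(mean(r2), 0.15)
})

test_that("plate-level identification fills the results table", {
  design <- defaultPlateDesign("matCmatB", iptg = c(0.1, 1), replicates = 2)
  plate <- generatePlate(design, seed = 4, sigma = 0,
                         growth = GrowthParams(lag = 0),
                         time = seq(0, by = 12, length.out = 150))
  fits <- identifyPlate(plate, order = 2)
  expect_equal(nrow(fits), 4)
  expect_true(all(c("K", "tau_1", "tau_2", "r_squared", "stable") %in%
                  colnames(fits)))
  ok <- fits$stable & fits$real_poles
  expect_true(all(fits$K[ok] > 0))
  expect_true(all(fits$tau_1[ok] >= fits$tau_2[ok], na.rm = TRUE))
  expect_true(all(fits$r_squared[ok] > 0.99))
})
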