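test_that("plate generation is deterministic under a fixed seed", {
  design <- defaultPlateDesign("matCmatB", iptg = c(0.1, 1),
                               replicates = 2)
  tm <- seq(0, by = 12, length.out = 60)
  p1 <- generatePlate(design, seed = 99, time = tm)
  p2 <- generatePlate(design, seed = 99, time = tm)
  expect_identical(odMatrix(p1), odMatrix(p2))
  expect_identical(rfpMatrix(p1), rfpMatrix(p2))
  p3 <- generatePlate(design, seed = 100, time = tm)
  expect_false(identical(rfpMatrix(p1), rfpMatrix(p3)))
})

test_that("zero measurement noise reproduces the cascade exactly", {
  design <- defaultPlateDesign("matCmatB", iptg = 1, replicates = 1)
  tm <- seq(0, by = 12, length.out = 80)
  gp <- GrowthParams(lag = 0)
  vmMap <- InductionMap()
  p <- generatePlate(design, growth = gp, sensor = SensorParams(),
                     vmMap = vmMap, sigma = 0, seed = 1, time = tm)
  sp <- SensorParams(vm = inductionToRate(1, vmMap))
  ref <- simulateSensorCascade(sp, logisticGrowth(gp, tm), tm,
                               dbiomass = logisticGrowthRate(gp, tm))
  expect_equal(rfpMatrix(p)[, 1], ref$R, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(odMatrix(p)[, 1], logisticGrowth(gp, tm),
               ignore_attr = TRUE)
})

test_that("a 96-well design yields 96 series on the full grid", {
  design <- defaultPlateDesign(c("matCmatB", "matCatoDA"), replicates = 8)
  expect_equal(nrow(design), 96)
  expect_equal(design$well_id[1:3], c("A1", "A2", "A3"))
  tm <- seq(0, by = 12, length.out = 120)
  p <- generatePlate(design, seed = 2, time = tm)
  expect_equal(dim(odMatrix(p)), c(120L, 96L))
  expect_equal(dim(rfpMatrix(p)), c(120L, 96L))
  expect_true(all(odMatrix(p) >= 0) && all(rfpMatrix(p) >= 0))
  expect_equal(samplingPeriod(p), 12)
  expect_error(generatePlate(design[0, ], seed = 1), "empty")
})

test_that("per-construct sensors and substrate gains reach the output", {
  design <- rbind(
    defaultPlateDesign("fast", iptg = 1, replicates = 1),
    defaultPlateDesign("slow", iptg = 1, replicates = 1))
  design$well_id <- c("A1", "A2")
  design$substrate <- c(FALSE, FALSE)
  tm <- seq(0, by = 12, length.out = 100)
  sensors <- list(fast = SensorParams(gammaR = 1 / 100),
                  slow = SensorParams(gammaR = 1 / 400))
  p <- generatePlate(design, seed = 3, sigma = 0, sensors = sensors,
                     time = tm, growth = GrowthParams(lag = 0))
  ## the slow reporter accumulates more fluorescence by the end
  expect_gt(rfpMatrix(p)[100, "A2"], rfpMatrix(p)[100, "A1"])
  ## substrate multiplies vm
  d2 <- defaultPlateDesign("matCmatB", iptg = 1, replicates = 1)
  d2s <- d2; d2s$substrate <- TRUE
  pN <- generatePlate(d2, seed = 4, sigma = 0, time = tm)
  pS <- generatePlate(d2s, seed = 4, sigma = 0, time = tm,
                      substrateGain = c(matCmatB = 1.5))
  expect_equal(unname(rfpMatrix(pS)[100, 1] / rfpMatrix(pN)[100, 1]),
               1.5, tolerance = 1e-6)
})

test_that("the FapR-depletion scenario changes the late response only", {
  design <- defaultPlateDesign("matCmatB", iptg = 1, replicates = 1)
  tm <- seq(0, by = 12, length.out = 120)
  gp <- GrowthParams(lag = 0)
  base <- generatePlate(design, seed = 5, sigma = 0, growth = gp,
                        time = tm)
  depl <- generatePlate(design, seed = 5, sigma = 0, growth = gp,
                        time = tm, depletionOD = 0.8,
                        depletionFactor = 0.25)
  X <- logisticGrowth(gp, tm)
  early <- X < 0.8
  expect_equal(rfpMatrix(depl)[early, 1], rfpMatrix(base)[early, 1],
               ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(rfpMatrix(depl)[!early, 1],
                                rfpMatrix(base)[!early, 1])))
  expect_true(all(rfpMatrix(depl) >= 0))
})

test_that("plate CSV round trip preserves data, metadata and grid", {
  design <- defaultPlateDesign("matCmatB", iptg = c(0.1, 1),
                               replicates = 2)
  tm <- seq(0, by = 12, length.out = 40)
  p <- generatePlate(design, seed = 7, time = tm)
  f <- tempfile(fileext = ".csv")
  writePlateCsv(p, f)
  q <- readPlateCsv(f)
  expect_equal(timeGrid(q), timeGrid(p))
  expect_equal(odMatrix(q), odMatrix(p), tolerance = 1e-12)
  expect_equal(rfpMatrix(q), rfpMatrix(p), tolerance = 1e-12)
  expect_equal(wellInfo(q)$construct, wellInfo(p)$construct)
  expect_equal(S4Vectors::metadata(q)$generator$seed, 7)
  ## identical writes are byte-identical
  f2 <- tempfile(fileext = ".csv")
  writePlateCsv(p, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2, paste0(c(f, f2), ".yaml")))
})

test_that("malformed plate CSVs are rejected with schema errors", {
  design <- defaultPlateDesign("matCmatB", iptg = 1, replicates = 2)
  tm <- seq(0, by = 12, length.out = 10)
  p <- generatePlate(design, seed = 8, time = tm)
  f <- tempfile(fileext = ".csv")
  writePlateCsv(p, f)
  ## drop one time point from one well: ragged grid
  df <- read.csv(f)
  df <- df[-5, ]
  f3 <- tempfile(fileext = ".csv")
  write.csv(df, f3, row.names = FALSE)
  expect_error(readPlateCsv(f3), "ragged")
  ## missing column
  f4 <- tempfile(fileext = ".csv")
  write.csv(df[, setdiff(colnames(df), "od600")], f4, row.names = FALSE)
  expect_error(readPlateCsv(f4), "od600")
  ## empty file
  f5 <- tempfile(fileext = ".csv")
  writeLines("", f5)
  expect_error(readPlateCsv(f5))
  unlink(c(f, f3, f4, f5, paste0(f, ".yaml")))
})

test_that("results CSV writing is deterministic with a stable schema", {
  res <- data.frame(construct = c("matCmatB", "mmsA"),
                    K = c(250.84, 300.53), tau_1 = c(290.11, 288.31),
                    tau_2 = c(12.69, 15.67))
  f1 <- tempfile(); f2 <- tempfile()
  writeResultsCsv(res, f1)
  writeResultsCsv(res, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(readLines(f1)[1], "construct,K,tau_1,tau_2")
  ## empty result set: header-only file
  f3 <- tempfile()
  writeResultsCsv(res[0, ], f3)
  expect_equal(length(readLines(f3)), 1L)
  unlink(c(f1, f2, f3))
})
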