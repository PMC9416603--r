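test_that("time-domain features match their printed definitions and oracles", {
  expect_identical(mav(c(-1, 2, -3)), 2)
  expect_identical(mav(numeric(10)), 0)
  expect_identical(sigVar(c(1, -1)), 2)
  expect_identical(rms(c(3, -3)), 3)
  expect_identical(zc(c(1, -1, 1, -1), 0.5), 3L)
  expect_identical(zc(rep(2, 10)), 0L)
  expect_identical(wamp(c(0, 1, 0), 0.5), 2L)
  expect_identical(wamp(c(0, 1, 0), 5), 0L)
  expect_identical(wl(c(0, 1, 0)), 2)
  expect_identical(wl(seq(0, 5, length.out = 11)), 5)
  set.seed(77)
  for (r in 1:20) {
    x <- rnorm(100, sd = runif(1, 0.1, 5))
    d <- runif(1, 0, 1)
    expect_equal(mav(x), oracleMAV(x))
    expect_equal(sigVar(x), oracleVAR(x))
    expect_equal(rms(x), oracleRMS(x))
    expect_equal(wl(x), oracleWL(x))
    expect_identical(as.integer(zc(x, d)), oracleZC(x, d))
    expect_identical(as.integer(wamp(x, d)), oracleWAMP(x, d))
  }
  expect_error(mav(numeric(0)), "empty")
  expect_error(sigVar(1), "at least 2")
})

test_that("spectral features are Parseval-consistent and oracle-exact", {
  rate <- 2000
  t <- (0:1199) / rate
  spec <- powerSpectrum(sin(2 * pi * 100 * t), rate)
  expect_equal(spec$frequency[which.max(spec$power)], 100,
               tolerance = rate / 1200 + 1e-9)
  expect_identical(sum(powerSpectrum(rep(5, 64), rate)$power), 0)
  set.seed(13)
  for (r in 1:10) {
    x <- rnorm(600)
    sp <- powerSpectrum(x, rate)
    expect_equal(sum(sp$power), oracleMeanSquare(x), tolerance = 1e-10)
    expect_equal(mdf(sp), oracleMDF(sp$frequency, sp$power))
    expect_equal(mnp(sp), oracleMNP(sp$power))
  }
  # flat spectrum -> middle bin; single tone -> tone bin
  flat <- list(frequency = 1:10, power = rep(1, 10), M = 10L)
  expect_identical(mdf(flat), 5L)
  tone <- list(frequency = 1:10, power = c(rep(0, 6), 1, 0, 0, 0), M = 10L)
  expect_identical(mdf(tone), 7L)
  expect_equal(mnp(flat), 1)
  expect_error(mdf(list(frequency = 1, power = 0, M = 1L)), "positive")
})

test_that("scale equivariance and rms >= mav hold on random windows", {
  set.seed(5)
  for (r in 1:100) {
    x <- rnorm(60, sd = runif(1, 0.01, 10))
    expect_gte(rms(x), mav(x))
  }
  x <- rnorm(200); a <- 3.7
  expect_equal(mav(a * x), a * mav(x))
  expect_equal(rms(a * x), a * rms(x))
  expect_equal(wl(a * x), a * wl(x))
  expect_identical(zc(a * x, a * 0.2), zc(x, 0.2))
  expect_identical(wamp(a * x, a * 0.2), wamp(x, 0.2))
})

test_that("extractManualFeatures assembles the documented column layout", {
  ws <- smallWindowSet()[1:20]
  f <- extractManualFeatures(ws)
  X <- featureValues(f)
  expect_identical(dim(X), c(20L, 4L * 8L + 3L * 6L))
  expect_false(anyNA(X))
  expect_true(all(is.finite(X)))
  # spot-check columns against single-channel calls
  x <- emg(ws)[3, 2, ]
  expect_equal(unname(X[3, "emg_TA_MAV"]), mav(x))
  expect_equal(unname(X[3, "emg_TA_WL"]), wl(x))
  expect_equal(unname(X[3, "emg_TA_ZC"]), as.numeric(zc(x, 0.01 * rms(x))))
  xi <- imu(ws)[5, 3, ]
  expect_equal(unname(X[5, "imu_angle_y_MDF"]), mdf(powerSpectrum(xi, 2000)))
  # condition groups
  expect_identical(ncol(featureValues(manualCondition(ws, "ETD"))), 24L)
  expect_identical(ncol(featureValues(manualCondition(ws, "ITF"))), 18L)
  expect_identical(ncol(featureValues(manualCondition(ws, "ETF+ITF"))), 50L)
  expect_identical(ncol(featureValues(manualCondition(ws, "IFD"))), 6L)
  expect_error(manualCondition(ws, "XYZ"), "unknown manual condition")
  expect_error(extractManualFeatures(ws, emgFeatures = "FOO"),
               "unknown feature")
})

test_that("feature matrices round-trip through CSV", {
  f <- extractManualFeatures(smallWindowSet()[1:10])
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(f, path)
  f2 <- readFeatureCSV(path)
  expect_equal(featureValues(f2), featureValues(f), tolerance = 1e-12)
  expect_identical(as.character(windowLabels(f2)),
                   as.character(windowLabels(f)))
  expect_identical(SummarizedExperiment::rowData(f2)$modality,
                   SummarizedExperiment::rowData(f)$modality)
})
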