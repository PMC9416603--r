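test_that("EMG band-pass matches its analytic response", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)[-1]
  trim <- 500:(length(t) - 500)
  # DC is annihilated
  expect_lt(max(abs(bandpassEMG(rep(2, length(t))))), 2e-6)
  # in-band 100 Hz tone passes at the designed gain (within 2% of unity)
  y <- bandpassEMG(sin(2 * pi * 100 * t))
  gain <- filterGain(100, "pass")
  amp <- max(abs(y[trim]))
  expect_lt(abs(amp - 1), 0.02)
  expect_lt(abs(amp - gain), 0.02)
  # 5 Hz stop-band tone is crushed below its analytic bound
  y5 <- bandpassEMG(sin(2 * pi * 5 * t))
  expect_lt(max(abs(y5[trim])), 0.1)
  expect_lt(max(abs(y5[trim])), filterGain(5, "pass") + 1e-3)
  expect_error(bandpassEMG(t, high = 1200), "Nyquist")
  expect_error(bandpassEMG(c(1, 2, 3)), "too short")
})

test_that("IMU low-pass matches its analytic response", {
  rate <- 200
  t <- seq(0, 5, by = 1 / rate)[-1]
  trim <- 100:(length(t) - 100)
  x <- rep(3, length(t))
  expect_lt(max(abs(lowpassIMU(x) - 3)), 1e-6)
  y2 <- lowpassIMU(sin(2 * pi * 2 * t))
  expect_lt(abs(max(abs(y2[trim])) - 1), 0.02)
  y50 <- lowpassIMU(sin(2 * pi * 50 * t))
  expect_lt(max(abs(y50[trim])), 0.05)
  expect_lt(max(abs(y50[trim])), filterGain(50, "low", rate = 200) + 1e-3)
  expect_error(lowpassIMU(t, cutoff = 150), "Nyquist")
})

test_that("in-band filtering is near idempotent", {
  t <- seq(0, 2, by = 1 / 2000)[-1]
  y1 <- bandpassEMG(sin(2 * pi * 100 * t))
  y2 <- bandpassEMG(y1)
  trim <- 500:(length(t) - 500)
  expect_lt(max(abs(y2[trim] - y1[trim])) / max(abs(y1[trim])), 0.02)
})

test_that("cubic-spline upsampling preserves knots and sample count", {
  x <- sin(seq_len(200) / 9) + 0.3 * cos(seq_len(200) / 3)
  y <- resampleCubic(x, 200, 2000)
  expect_length(y, 2000L)
  expect_lt(max(abs(y[seq(1, 2000, by = 10)] - x)), 1e-9)
  # smooth 1 Hz sine is reconstructed to high accuracy
  tin <- (0:199) / 200
  tout <- (0:1999) / 2000
  ys <- resampleCubic(sin(2 * pi * tin), 200, 2000)
  inner <- tout <= max(tin)           # exclude the extrapolated tail
  expect_lt(max(abs(ys[inner] - sin(2 * pi * tout[inner]))), 1e-4)
  expect_error(resampleCubic(x, 200, 300), "integer multiple")
  expect_error(resampleCubic(x[1:3], 200, 2000), "at least 4")
})

test_that("segmentation yields aligned, correctly counted window pairs", {
  b <- generateRecording(defaultGaitParams("running"), "running", 3.5, 21,
                         meta = list(sourceId = "r1", subject = "S1"))
  # 3.5 s -> 7000 samples, minus 2 x 500 trim = 6000 -> 10 windows
  ws <- buildWindowSet(b)
  expect_s4_class(ws, "WindowSet")
  expect_identical(nWindows(ws), 10L)
  expect_identical(dim(emg(ws)), c(10L, 4L, 600L))
  expect_identical(dim(imu(ws)), c(10L, 3L, 600L))
  expect_identical(unique(as.character(windowLabels(ws))), "running")
  # overlapping stride: floor((6000-600)/300)+1 = 19
  ws2 <- buildWindowSet(b, stride = 300L)
  expect_identical(nWindows(ws2), 19L)
  # paired windows share start indices (time alignment after upsampling)
  expect_identical(ws@startIndex, seq(0L, 5400L, by = 600L))
  expect_error(buildWindowSet(generateRecording(defaultGaitParams("running"),
                                                "running", 0.78, 1)),
               "shorter than one window")
})

test_that("7:1:2 split is stratified, exhaustive and seed-stable", {
  ws <- smallWindowSet()
  n <- nWindows(ws)
  expect_identical(sum(table(windowSplit(ws))[c("train", "val", "test")]),
                   as.integer(n))
  # per-mode train fraction close to 0.7
  for (m in motionModes()) {
    sel <- windowLabels(ws) == m
    frac <- mean(windowSplit(ws)[sel] == "train")
    expect_gte(frac, 0.65); expect_lte(frac, 0.75)
  }
  ws2 <- assignSplit(ws, seed = 12)
  expect_identical(windowSplit(ws2), windowSplit(ws))
  ws3 <- assignSplit(ws, seed = 99)
  expect_false(identical(windowSplit(ws3), windowSplit(ws)))
  # exact 70/10/20 on a balanced 100-window subset
  idx <- unlist(lapply(motionModes(),
                       function(m) which(windowLabels(ws) == m)[1:25]))
  sub <- assignSplit(ws[idx], seed = 5)
  expect_identical(as.integer(table(windowSplit(sub))[c("train", "val",
                                                        "test")]),
                   c(70L, 10L, 20L))
  expect_error(assignSplit(ws[1:5], seed = 1), "at least 10")
})

test_that("iemg and cycleSimilarity agree with their oracles", {
  expect_identical(iemg(c(1, -2, 3)), 6)
  expect_identical(iemg(numeric(5)), 0)
  set.seed(31)
  x <- rnorm(100)
  expect_equal(iemg(x), oracleIEMG(x))
  expect_error(iemg(numeric(0)), "empty")

  c1 <- sin(1:50); c2 <- cos(1:50)
  m <- cycleSimilarity(list(c1, c1, -c1))
  expect_equal(unname(m[1, 2]), 1)
  expect_equal(unname(m[1, 3]), -1)
  m2 <- cycleSimilarity(list(c1, c2))
  expect_equal(unname(m2[1, 2]), oraclePearson(c1, c2), tolerance = 1e-12)
  expect_true(isSymmetric(m2))
  expect_error(cycleSimilarity(list(c1, rep(1, 50))), "constant")
  expect_error(cycleSimilarity(list(c1)), "at least 2")
})

test_that("QC on generator defaults passes its thresholds across seeds", {
  for (s in 1:5) {
    b <- generateRecording(defaultGaitParams("running"), "running", 12,
                           100 + s)
    qc <- qcReport(b, seed = s)
    expect_true(all(qc@passFlags))
    expect_true(all(qc@iemgStats$sd >= 0))
    for (m in qc@similarity)
      expect_true(all(m >= -1 & m <= 1 + 1e-12))
  }
})

test_that("window sets round-trip through the container file", {
  ws <- smallWindowSet()[1:12]
  path <- withr::local_tempfile(fileext = ".rds")
  saveWindowSet(ws, path)
  ws2 <- loadWindowSet(path)
  expect_identical(emg(ws2), emg(ws))
  expect_identical(windowLabels(ws2), windowLabels(ws))
})
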