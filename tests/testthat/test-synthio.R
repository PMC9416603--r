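test_that("default parameters are fixed, distinguishable and band-correct", {
  for (m in motionModes()) {
    p1 <- defaultGaitParams(m)
    p2 <- defaultGaitParams(m)
    expect_identical(p1, p2)
    expect_identical(p1@emgBand, c(20, 500))
  }
  expect_gt(defaultGaitParams("running")@cadence,
            defaultGaitParams("level_walk")@cadence)
  cadences <- vapply(motionModes(), function(m) defaultGaitParams(m)@cadence,
                     numeric(1))
  expect_length(unique(cadences), 4L)
  # running has the largest EMG amplitudes
  peak <- function(m) max(vapply(defaultGaitParams(m)@muscleEnvelopes,
                                 function(e) max(e$amplitude), numeric(1)))
  expect_true(all(peak("running") > vapply(setdiff(motionModes(), "running"),
                                           peak, numeric(1))))
  expect_error(defaultGaitParams("jumping"), "unknown motion mode")
})

test_that("generateRecording is seed-reproducible with correct geometry", {
  p <- defaultGaitParams("level_walk")
  b1 <- generateRecording(p, "level_walk", 4, 1)
  b2 <- generateRecording(p, "level_walk", 4, 1)
  expect_identical(emg(b1), emg(b2))
  expect_identical(imu(b1), imu(b2))
  expect_identical(dim(emg(b1)), c(4L, 8000L))
  expect_identical(dim(imu(b1)), c(3L, 800L))
  expect_false(anyNA(emg(b1)))
  b3 <- generateRecording(p, "level_walk", 4, 2)
  expect_false(identical(emg(b1), emg(b3)))
  expect_error(generateRecording(p, "level_walk", -1, 1), "positive")
  expect_error(generateRecording(p, "level_walk", 0.5, 1), "two gait cycles")
})

test_that("noise-free, jitter-free IMU cycles are exactly periodic", {
  p <- defaultGaitParams("level_walk")
  p@cycleJitter <- 0
  p@imuNoiseSD <- c(0, 0, 0)
  p@emgNoiseFloor <- 0
  b <- generateRecording(p, "level_walk", 15, 3)
  ang <- imu(b)["angle_y", ]
  # compare cycles at exact-phase spacing: 9 cycles = 1000 samples at 1.8 Hz
  span <- round(9 * b@rateIMU / p@cadence)
  c1 <- ang[1:span]
  c2 <- ang[(span + 1):(2 * span)]
  expect_gt(cor(c1, c2), 1 - 1e-9)
})

test_that("default IMU angle cycles exceed the 0.85 similarity regime", {
  b <- generateRecording(defaultGaitParams("running"), "running", 30, 7)
  sig <- lowpassIMU(imu(b)["angle_y", ], rate = 200)
  cyc <- extractCycles(sig)$cycles
  set.seed(7)
  pick <- sample(ncol(cyc), 5)
  sims <- c()
  for (i in 1:4) for (j in (i + 1):5)
    sims <- c(sims, oraclePearson(cyc[, pick[i]], cyc[, pick[j]]))
  expect_gte(mean(sims), 0.85)
})

test_that("EMG power is confined to the carrier band", {
  p <- defaultGaitParams("level_walk")
  p@emgNoiseFloor <- 0
  b <- generateRecording(p, "level_walk", 6, 5)
  for (ch in 1:4) {
    spec <- powerSpectrum(emg(b)[ch, ], 2000)
    inBand <- spec$frequency >= p@emgBand[1] & spec$frequency <= p@emgBand[2]
    expect_gte(sum(spec$power[inBand]) / sum(spec$power), 0.95)
  }
})

test_that("generateDataset enumerates, labels and de-duplicates bundles", {
  prof <- defaultSubjectProfiles(2)
  modes <- c("running", "stair_ascent")
  ds <- generateDataset(prof, modes, repsPerMode = 2, duration = 3, seed = 5)
  expect_length(ds, 2 * 2 * 2)
  expect_identical(vapply(ds, motionMode, character(1)),
                   rep(rep(modes, each = 2), 2))
  # all pairwise distinct
  sigs <- vapply(ds, function(b) paste(head(emg(b)[1, ], 5), collapse = ","),
                 character(1))
  expect_length(unique(sigs), length(ds))
  expect_error(generateDataset(list(), modes), "non-empty")
  expect_error(generateDataset(prof, character()), "non-empty")
})

test_that("a trivial RMS nearest-centroid classifier beats 70% on defaults", {
  # the synthetic task must be learnable but not degenerate: per-window RMS
  # of the 7 channels alone separates the modes well above chance
  ws <- smallWindowSet()
  rmsFeat <- cbind(apply(emg(ws), c(1, 2), function(v) sqrt(mean(v^2))),
                   apply(imu(ws), c(1, 2), function(v) sqrt(mean(v^2))))
  tr <- windowSplit(ws) == "train"
  te <- windowSplit(ws) == "test"
  mu <- colMeans(rmsFeat[tr, ])
  sg <- apply(rmsFeat[tr, ], 2, sd)
  Z <- sweep(sweep(rmsFeat, 2, mu), 2, sg, "/")
  cent <- sapply(motionModes(), function(m)
    colMeans(Z[tr & windowLabels(ws) == m, , drop = FALSE]))
  d <- as.matrix(dist(rbind(t(cent), Z[te, ])))[-(1:4), 1:4]
  pred <- motionModes()[apply(d, 1, which.min)]
  expect_gt(mean(pred == as.character(windowLabels(ws)[te])), 0.70)
})

test_that("cycle similarity does not improve when jitter grows", {
  jgrid <- c(0.01, 0.05, 0.15)
  meanSim <- function(jit, seed) {
    p <- defaultGaitParams("level_walk")
    p@cycleJitter <- jit
    b <- generateRecording(p, "level_walk", 20, seed)
    cyc <- extractCycles(lowpassIMU(imu(b)["angle_y", ], rate = 200))$cycles
    m <- cycleSimilarity(cyc)
    mean(m[upper.tri(m)])
  }
  sims <- sapply(1:10, function(s) sapply(jgrid, meanSim, seed = s))
  avg <- rowMeans(sims)
  expect_true(all(diff(avg) <= 0))
})

test_that("recordings round-trip through the CSV dialect", {
  b <- generateRecording(defaultGaitParams("ramp_ascent"), "ramp_ascent", 3,
                         9, meta = list(sourceId = "demo", subject = "S1"))
  dir <- withr::local_tempdir()
  pre <- writeRecording(b, dir)
  expect_true(file.exists(paste0(pre, "_emg.csv")))
  b2 <- readRecording(pre)
  expect_equal(emg(b2), emg(b), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(imu(b2), imu(b), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(motionMode(b2), "ramp_ascent")
})
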