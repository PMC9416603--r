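test_that("branch geometry reproduces the printed 160/320/32 chain", {
  se <- outputShape(branchSpec("emg"))
  expect_identical(se$conv1, c(4L, 500L, 16L))
  expect_identical(se$pool1, c(4L, 50L, 16L))
  expect_identical(se$conv2, c(2L, 40L, 8L))
  expect_identical(se$pool2, c(1L, 20L, 8L))
  expect_identical(se$flattened, 160L)
  si <- outputShape(branchSpec("imu"))
  expect_identical(si$flattened, 160L)
  sf <- outputShape(branchSpec("fused"))
  expect_identical(sf$flattened, 320L)
  spec <- dualStreamSpec()
  expect_identical(spec$fusionWidth, 320L)
  expect_identical(spec$fcWidth, 32L)
  # negative control: any stride/padding deviation breaks the identity --
  # here, changing kernel or pool sizes shifts the flattened width
  b <- branchSpec("emg"); b$conv1 <- c(1L, 102L)
  expect_false(outputShape(b)$flattened == 160L)
  b2 <- branchSpec("emg"); b2$pool1 <- c(1L, 9L)
  expect_false(outputShape(b2)$flattened == 160L)
  b3 <- branchSpec("emg"); b3$conv1 <- c(1L, 700L)
  expect_error(outputShape(b3), "larger than input")
})

test_that("untrained models produce valid seeded probabilities", {
  ws <- smallWindowSet()[1:8]
  m1 <- buildDualStream(seed = 5)
  m2 <- buildDualStream(seed = 5)
  p1 <- predictProb(m1, ws)
  p2 <- predictProb(m2, ws)
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 8), tolerance = 1e-6)
  m3 <- buildDualStream(seed = 6)
  expect_false(identical(predictProb(m3, ws), p1))
  # zero inputs stay finite
  ws0 <- ws
  ws0@emg[] <- 0; ws0@imu[] <- 0
  p0 <- predictProb(m1, ws0)
  expect_true(all(is.finite(p0)))
  # single-stream variants accept their inputs
  for (arch in c("emg", "imu", "fused")) {
    ms <- buildSingleStream(arch, seed = 1)
    ps <- predictProb(ms, ws)
    expect_equal(unname(rowSums(ps)), rep(1, 8), tolerance = 1e-6)
  }
})

test_that("reference-path gradients match finite differences", {
  # tiny architecture exercised through the double-precision reference
  # implementation of the same forward/backward pass
  spec <- list(main = list(modality = "emg", inChannels = 2L, inLength = 20L,
                           conv1 = c(1L, 5L), depth1 = 3L, pool1 = c(1L, 2L),
                           conv2 = c(2L, 3L), depth2 = 2L, pool2 = c(1L, 2L)),
               fcWidth = 4L, nClasses = 3L, fcRelu = TRUE)
  plans <- list(main = DualStreamGait:::.branchPlan(spec$main))
  set.seed(8)
  params <- list(main = DualStreamGait:::.initBranchParams(plans$main))
  fusion <- plans$main$flattened
  params$head <- list(Wfc = matrix(rnorm(4 * fusion, sd = 0.3), 4, fusion),
                      bfc = rnorm(4, sd = 0.1),
                      Wout = matrix(rnorm(3 * 4, sd = 0.3), 3, 4),
                      bout = rnorm(3, sd = 0.1))
  X <- list(main = matrix(rnorm(40 * 6), 40, 6))
  y <- c(1L, 2L, 3L, 1L, 2L, 3L)
  lossAt <- function(par) {
    fw <- DualStreamGait:::.modelForwardRef(par, plans, X, TRUE)
    -mean(log(fw$prob[cbind(y, 1:6)]))
  }
  fw <- DualStreamGait:::.modelForwardRef(params, plans, X, TRUE)
  gr <- DualStreamGait:::.modelBackwardRef(params, plans, fw, y, TRUE)
  eps <- 1e-6
  for (grp in c("main", "head")) {
    for (pn in names(params[[grp]])) {
      w <- params[[grp]][[pn]]
      for (probe in seq_len(min(4, length(w)))) {
        i <- ((probe * 7) %% length(w)) + 1L
        pp <- params; pp[[grp]][[pn]][i] <- w[i] + eps
        pm <- params; pm[[grp]][[pn]][i] <- w[i] - eps
        num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
        expect_equal(gr[[grp]][[pn]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("the single-precision engine agrees with the reference path", {
  spec <- branchSpec("imu")
  plan <- DualStreamGait:::.branchPlan(spec)
  set.seed(17)
  pars <- DualStreamGait:::.initBranchParams(plan)
  X <- matrix(rnorm(3 * 600 * 5), 3 * 600, 5)
  fwF <- DualStreamGait:::.branchForward(X, pars, plan, keepCache = TRUE)
  fwD <- DualStreamGait:::.branchForwardRef(X, pars, plan)
  expect_equal(fwF$F, fwD$F, tolerance = 1e-5)
  dF <- matrix(rnorm(length(fwD$F)), nrow(fwD$F), ncol(fwD$F))
  grF <- DualStreamGait:::.branchBackward(dF, fwF, pars, plan)
  grD <- DualStreamGait:::.branchBackwardRef(dF, fwD, pars, plan)
  for (pn in c("W1", "b1", "W2", "b2")) {
    denom <- max(abs(grD[[pn]])) + 1e-8
    expect_lt(max(abs(grF[[pn]] - grD[[pn]])) / denom, 1e-4)
  }
})

test_that("training reduces loss, is seed-deterministic, and learns", {
  ws <- smallWindowSet()
  ex1 <- trainExtractor(buildDualStream(seed = 3), ws, epochs = 5, seed = 3)
  h1 <- trainingHistory(ex1)
  expect_identical(nrow(h1), 5L)
  expect_lt(h1$loss[5], h1$loss[1])
  expect_gt(max(h1$trainAcc), h1$trainAcc[1] - 1e-9)
  ex2 <- trainExtractor(buildDualStream(seed = 3), ws, epochs = 5, seed = 3)
  expect_identical(trainingHistory(ex2), h1)
  expect_error(trainExtractor(buildDualStream(seed = 1),
                              ws[windowLabels(ws) == "running"][1:12],
                              epochs = 1),
               "2 classes")
})

test_that("extraction taps give the documented widths in window order", {
  ws <- smallWindowSet()
  ex <- trainExtractor(buildDualStream(seed = 4), ws, epochs = 3, seed = 4)
  sub <- ws[1:50]
  f32 <- extractFeatures(ex, sub, tap = "fc32")
  expect_identical(dim(featureValues(f32)), c(50L, 32L))
  f320 <- extractFeatures(ex, sub, tap = "fusion320")
  expect_identical(dim(featureValues(f320)), c(50L, 320L))
  expect_identical(featureValues(extractFeatures(ex, sub)),
                   featureValues(f32))
  # permuting windows permutes rows identically
  perm <- c(17, 3, 29, 8, 1)
  fp <- extractFeatures(ex, sub[perm])
  expect_equal(featureValues(fp), featureValues(f32)[perm, ],
               ignore_attr = TRUE)
  # checkpoint round trip
  path <- withr::local_tempfile(fileext = ".rds")
  saveExtractor(ex, path)
  ex2 <- loadExtractor(path)
  expect_identical(featureValues(extractFeatures(ex2, sub)),
                   featureValues(f32))
  expect_warning(extractFeatures(buildDualStream(seed = 1), sub),
                 "not been trained")
})

test_that("trained fc32 features separate held-out windows far above chance", {
  ws <- defaultWindowSet()
  ex <- defaultDualExtractor()
  h <- trainingHistory(ex)
  expect_gt(tail(h$valAcc, 1), 0.9)
  f <- extractFeatures(ex, ws)
  X <- featureValues(f)
  te <- windowSplit(ws) == "test"
  tr <- windowSplit(ws) == "train"
  cent <- sapply(motionModes(), function(m)
    colMeans(X[tr & windowLabels(ws) == m, , drop = FALSE]))
  d <- as.matrix(dist(rbind(t(cent), X[te, ])))[-(1:4), 1:4]
  pred <- motionModes()[apply(d, 1, which.min)]
  acc <- mean(pred == as.character(windowLabels(ws)[te]))
  expect_gte(acc, 0.25 + 0.40)
})
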