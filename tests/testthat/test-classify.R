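test_that("cross-validation separates separable clusters and respects folds", {
  set.seed(10)
  X <- rbind(matrix(rnorm(200, 0), 50, 4), matrix(rnorm(200, 8), 50, 4))
  y <- factor(rep(c("a", "b"), each = 50))
  for (kind in c("SVM", "KNN", "DT", "RF")) {
    r <- crossValidate(X, y, kind = kind, seed = 3)
    expect_equal(meanAccuracy(r), 1)
    expect_length(foldAccuracy(r), 5L)
    expect_identical(sum(r@confusion), 100L)
    expect_identical(as.integer(rowSums(r@confusion)), c(50L, 50L))
  }
  foldid <- DualStreamGait:::.makeFolds(y, 5, 3)
  expect_identical(as.integer(table(foldid)), rep(20L, 5))
  # every fold stratified
  expect_true(all(table(foldid, y) == 10))
  expect_identical(DualStreamGait:::.makeFolds(y, 5, 3), foldid)
  expect_error(crossValidate(X[c(1:4, 51:54), ], y[c(1:4, 51:54)],
                             kind = "SVM"),
               "at least folds")
  expect_error(crossValidate(X, y, kind = "LDA"), "unknown classifier")
})

test_that("permuted labels drop every classifier to chance level", {
  set.seed(99)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)   # label-independent features
  y0 <- factor(rep(motionModes(), length.out = n))
  accs <- sapply(1:10, function(s) {
    set.seed(s)
    y <- sample(y0)
    sapply(c("SVM", "KNN", "DT", "RF"), function(k)
      meanAccuracy(crossValidate(X, y, kind = k, seed = s)))
  })
  means <- rowMeans(accs)
  for (k in rownames(accs)) {
    expect_gte(means[[k]], 0.15)
    expect_lte(means[[k]], 0.35)
  }
})

test_that("a label canary is caught only when present (no hidden leakage)", {
  set.seed(7)
  n <- 120
  y <- factor(rep(motionModes(), length.out = n))
  noise <- matrix(rnorm(n * 5), n, 5)
  canary <- cbind(noise, canary = as.integer(y))
  accWith <- meanAccuracy(crossValidate(canary, y, kind = "DT", seed = 2))
  accWithout <- meanAccuracy(crossValidate(noise, y, kind = "DT", seed = 2))
  expect_equal(accWith, 1)
  expect_lt(accWithout, 0.45)   # chance is 0.25
})

test_that("comparison grid produces paired reports per condition", {
  ws <- smallWindowSet()
  reports <- runComparison(ws, conditions = c("ETD", "ITF", "ETF+ITF"),
                           classifiers = c("KNN", "DT"), seed = 5)
  expect_length(reports, 6L)
  tab <- comparisonTable(reports)
  expect_identical(nrow(tab), 6L)
  expect_true(all(tab$meanAccuracy >= 0 & tab$meanAccuracy <= 1))
  # identical folds across conditions: confusion row sums agree
  expect_identical(rowSums(reports[["ETD.KNN"]]@confusion),
                   rowSums(reports[["ITF.KNN"]]@confusion))
  expect_error(runComparison(ws, conditions = "BAD"), "unknown")
  expect_error(runComparison(ws, classifiers = "MLP"), "unknown classifier")
})

test_that("evaluation reports round-trip through JSON", {
  set.seed(2)
  X <- matrix(rnorm(240), 60, 4)
  y <- factor(rep(motionModes(), each = 15))
  r <- crossValidate(X, y, kind = "KNN", seed = 11, condition = "demo")
  path <- withr::local_tempfile(fileext = ".json")
  writeReport(r, path)
  r2 <- readReport(path)
  expect_identical(r2@condition, r@condition)
  expect_identical(r2@classifier, r@classifier)
  expect_equal(r2@foldAccuracy, r@foldAccuracy, tolerance = 1e-15)
  expect_identical(unname(r2@confusion), unname(r@confusion))
})

test_that("top-feature coordinates use the three heaviest features", {
  set.seed(4)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  wv <- new("ReliefFWeights",
            weights = c(f1 = 0.1, f2 = 0.9, f3 = 0.5, f4 = 0.2, f5 = 0.7,
                        f6 = 0),
            kept = integer(), threshold = 0.1,
            priors = c(a = 0.5, b = 0.5), k = 1L)
  co <- topFeatureCoords(X, wv, y = rep(c("a", "b"), 25))
  expect_identical(names(co), c("window", "x", "y", "z", "label"))
  expect_identical(co$x, X[, "f2"])
  expect_identical(co$y, X[, "f5"])
  expect_identical(co$z, X[, "f3"])
})
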