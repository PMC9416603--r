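test_that("reliefDiff follows the range-normalised / discrete definitions", {
  expect_identical(reliefDiff(0.3, 0.3, range = 2), 0)
  expect_identical(reliefDiff(1, 0, range = 1), 1)   # endpoints
  expect_identical(reliefDiff("a", "b", discrete = TRUE), 1)
  expect_identical(reliefDiff("a", "a", discrete = TRUE), 0)
  expect_identical(reliefDiff(5, 9, range = 0), 0)   # constant feature
  set.seed(3)
  for (r in 1:20) {
    s1 <- runif(1); s2 <- runif(1); rg <- runif(1, 0.5, 3)
    expect_equal(reliefDiff(s1, s2, rg), abs(s1 - s2) / rg)
  }
})

test_that("weights match the exhaustive oracle on small datasets", {
  set.seed(42)
  for (r in 1:8) {
    n <- sample(10:30, 1)
    p <- sample(2:5, 1)
    ncl <- sample(2:3, 1)
    y <- factor(rep_len(letters[1:ncl], n))
    X <- matrix(rnorm(n * p), n, p)
    k <- sample(1:3, 1)
    wv <- relieffWeights(X, y, k = k)
    expect_equal(unname(featureWeights(wv)), oracleReliefF(X, y, k),
                 tolerance = 1e-10)
  }
})

test_that("separating features are rewarded, constants and duplicates behave", {
  y <- factor(rep(c("a", "b"), each = 6))
  sep <- c(rnorm(6, -3, 0.1), rnorm(6, 3, 0.1))
  X <- cbind(sep = sep, const = rep(1, 12), dup1 = sep, dup2 = sep)
  wv <- relieffWeights(X, y, k = 1)
  w <- featureWeights(wv)
  expect_gt(w[["sep"]], 0)
  expect_identical(w[["const"]], 0)
  expect_identical(w[["dup1"]], w[["dup2"]])
  expect_true(all(abs(w) <= 1))
  # priors
  expect_equal(sum(wv@priors), 1)
  expect_equal(unname(wv@priors), c(0.5, 0.5))
})

test_that("relevance ordering and scale invariance hold across seeds", {
  for (s in 1:10) {
    set.seed(s)
    y <- factor(rep(c("a", "b"), each = 15))
    strong <- c(rnorm(15, 0), rnorm(15, 4))   # well separated
    weak <- c(rnorm(15, 0), rnorm(15, 0.8))   # weakly separated
    X <- cbind(A = strong, B = weak)
    w <- featureWeights(relieffWeights(X, y, k = 3))
    expect_gt(w[["A"]], w[["B"]])
    Xs <- X; Xs[, "A"] <- X[, "A"] * 137.5
    ws <- featureWeights(relieffWeights(Xs, y, k = 3))
    expect_equal(ws[["A"]], w[["A"]], tolerance = 1e-12)
  }
})

test_that("determinism and error handling of the weight computation", {
  set.seed(9)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- factor(rep(c("a", "b"), 20))
  expect_identical(relieffWeights(X, y, k = 5),
                   relieffWeights(X, y, k = 5))
  # seeded subsampling is reproducible
  w1 <- relieffWeights(X, y, k = 5, m = 10, seed = 4)
  w2 <- relieffWeights(X, y, k = 5, m = 10, seed = 4)
  expect_identical(featureWeights(w1), featureWeights(w2))
  expect_error(relieffWeights(X, y, k = 25), "more than k")
  expect_error(relieffWeights(X, factor(rep("a", 40)), k = 2),
               "at least 2 classes")
})

test_that("selection keeps exactly the features reaching the threshold", {
  set.seed(21)
  X <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  wv <- new("ReliefFWeights",
            weights = c(f1 = 0.5, f2 = 0.05, f3 = 0.12, f4 = -0.2, f5 = 0.1),
            kept = integer(), threshold = 0.1,
            priors = c(a = 0.5, b = 0.5), k = 3L)
  kept <- selectFeatures(X, wv)
  expect_identical(colnames(kept), c("f1", "f3", "f5"))
  expect_identical(sum(wv@weights >= 0.1), ncol(kept))
  # all weights pass -> identity
  wvAll <- wv; wvAll@weights[] <- 0.5
  expect_identical(ncol(selectFeatures(X, wvAll)), 5L)
  # threshold above the maximum -> error advising a lower threshold
  expect_error(selectFeatures(X, wv, threshold = 0.9), "lower the threshold")
  expect_warning(selectFeatures(X, wv, threshold = 0.4), "survive")
})
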