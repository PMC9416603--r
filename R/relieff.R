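# Multi-class ReliefF feature weighting.  For each sampled instance S the
# weight of feature N is decreased by the mean range-normalised difference
# to the k nearest same-class hits H_i and increased by the prior-weighted
# mean difference to the k nearest misses M_j(C) of every other class C:
#
#   W(N) <- W(N) - 1/(mk) sum_i diff(N, S, H_i)
#               + 1/(mk) sum_{C != class(S)} P(C)/(1 - P(class(S)))
#                         sum_j diff(N, S, M_j(C))
#
# with diff(N, S1, S2) = |S1(N) - S2(N)| / (max(N) - min(N)) for continuous
# features and the 0/1 indicator for discrete ones.

#' Range-normalised feature difference
#'
#' @param s1,s2 Feature values (scalars or equal-length vectors).
#' @param range Feature range \code{max - min} (continuous case).  Zero-range
#'   (constant) features give 0 rather than dividing by zero.
#' @param discrete If TRUE, returns the 0/1 disagreement indicator instead.
#' @return Difference in [0, 1] (elementwise).
#' @examples
#' reliefDiff(0.2, 0.7, range = 1)   # 0.5
#' @export
reliefDiff <- function(s1, s2, range = 1, discrete = FALSE) {
  if (discrete) return(as.numeric(s1 != s2))
  out <- abs(s1 - s2) / range
  out[range == 0] <- 0
  out
}

#' ReliefF feature weights
#'
#' Computes W(N) for every feature by iterating over m sampled instances
#' (default: all rows, in order, for determinism), finding the k nearest
#' hits and the k nearest misses per other class with Euclidean distance on
#' per-feature max--min-normalised values (so the metric agrees with the
#' range-normalised diff), and accumulating the weight update above.
#' Neighbour ties break towards the lowest row index; an instance is never
#' its own hit.  With range normalisation every |W(N)| <= 1.
#'
#' @param X Windows x features numeric matrix, or a
#'   \linkS4class{MotionFeatures}.
#' @param y Class labels (ignored, taken from colData, when X is a
#'   MotionFeatures).
#' @param k Neighbours per class (default 10); every class must have more
#'   than k members.
#' @param m Number of sampled instances; NULL (default) uses every row
#'   deterministically, otherwise a seeded sample without replacement.
#' @param threshold Selection cutoff stored for [selectFeatures()]
#'   (default 0.1).
#' @param seed Seed used only when \code{m} is given.
#' @return A \linkS4class{ReliefFWeights}.
#' @export
relieffWeights <- function(X, y = NULL, k = 10L, m = NULL, threshold = 0.1,
                           seed = 1L) {
  if (is(X, "MotionFeatures")) {
    y <- windowLabels(X)
    X <- featureValues(X)
  }
  stopifnot(is.matrix(X), !anyNA(X))
  y <- droplevels(as.factor(y))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  tab <- table(y)
  if (any(tab <= k))
    stop("every class needs more than k = ", k, " members; smallest class ",
         "has ", min(tab), " — lower k or add data")
  rng <- apply(X, 2, function(col) diff(range(col)))
  Z <- X
  ok <- rng > 0
  Z[, ok] <- sweep(sweep(X[, ok, drop = FALSE], 2,
                         apply(X[, ok, drop = FALSE], 2, min)),
                   2, rng[ok], "/")
  Z[, !ok] <- 0
  D <- as.matrix(dist(Z))
  priors <- as.numeric(tab) / n
  names(priors) <- names(tab)
  sel <- if (is.null(m)) seq_len(n)
         else .withSeed(seed, sort(sample.int(n, min(m, n))))
  mEff <- length(sel)
  W <- numeric(p)
  classIdx <- split(seq_len(n), y)
  for (s in sel) {
    cs <- as.character(y[s])
    # hits: k nearest same-class, excluding self; ties -> lowest index
    hs <- classIdx[[cs]]
    hs <- hs[hs != s]
    hits <- hs[order(D[s, hs], hs)][seq_len(k)]
    W <- W - colSums(abs(Z[hits, , drop = FALSE] -
                           rep(Z[s, ], each = k))) / (mEff * k)
    pS <- priors[[cs]]
    for (co in setdiff(names(classIdx), cs)) {
      ms <- classIdx[[co]]
      miss <- ms[order(D[s, ms], ms)][seq_len(k)]
      W <- W + (priors[[co]] / (1 - pS)) *
        colSums(abs(Z[miss, , drop = FALSE] -
                      rep(Z[s, ], each = k))) / (mEff * k)
    }
  }
  names(W) <- colnames(X)
  new("ReliefFWeights", weights = W,
      kept = which(W >= threshold), threshold = threshold,
      priors = priors, k = as.integer(k))
}

#' Select features by ReliefF weight
#'
#' Keeps exactly the columns whose weight reaches the threshold, preserving
#' order.  Warns when fewer than 3 features survive; errors (suggesting a
#' lower threshold) when none do.
#'
#' @param X Windows x features matrix or \linkS4class{MotionFeatures}.
#' @param wv A \linkS4class{ReliefFWeights} computed on the same columns.
#' @param threshold Weight cutoff; defaults to the one stored in \code{wv}.
#' @return Object of the same type as \code{X}, reduced to the surviving
#'   columns.
#' @export
selectFeatures <- function(X, wv, threshold = wv@threshold) {
  stopifnot(is(wv, "ReliefFWeights"))
  p <- if (is(X, "MotionFeatures")) nrow(X) else ncol(X)
  if (length(wv@weights) != p)
    stop("weight vector length does not match feature count")
  keep <- which(wv@weights >= threshold)
  if (length(keep) == 0L)
    stop("no features reach weight ", threshold,
         "; lower the threshold (max weight is ",
         signif(max(wv@weights), 3), ")")
  if (length(keep) < 3L)
    warning("only ", length(keep), " feature(s) survive selection")
  if (is(X, "MotionFeatures")) X[keep, ] else X[, keep, drop = FALSE]
}
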