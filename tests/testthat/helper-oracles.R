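# Independent brute-force oracles used to validate the package
# implementations.  These are deliberately naive (explicit loops, direct
# formula transcription) and share no code with the package.

# Pearson correlation written out from the covariance/SD definition.
oraclePearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2))
  num / den
}

# Direct-summation versions of the manual features.
oracleMAV <- function(x) sum(abs(x)) / length(x)
oracleVAR <- function(x) { s <- 0; for (v in x) s <- s + v * v; s / (length(x) - 1) }
oracleRMS <- function(x) sqrt(sum(x * x) / length(x))
oracleWL <- function(x) { s <- 0; for (i in 1:(length(x) - 1)) s <- s + abs(x[i + 1] - x[i]); s }
oracleZC <- function(x, d) {
  cnt <- 0L
  for (i in 1:(length(x) - 1))
    if (sign(x[i] * x[i + 1]) < 0 && abs(x[i] - x[i + 1]) > d) cnt <- cnt + 1L
  cnt
}
oracleWAMP <- function(x, thr) {
  cnt <- 0L
  for (i in 1:(length(x) - 1))
    if (abs(x[i] - x[i + 1]) >= thr) cnt <- cnt + 1L
  cnt
}
oracleIEMG <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s }
oracleMDF <- function(freq, pow) {
  tot <- sum(pow); cum <- 0
  for (i in seq_along(pow)) {
    cum <- cum + pow[i]
    if (cum >= tot / 2) return(freq[i])
  }
}
oracleMNP <- function(pow) sum(pow) / length(pow)

# Exhaustive ReliefF: explicit transcription of the weight update
#   W(N) <- W(N) - 1/(mk) sum_i diff(N,S,H_i)
#         + 1/(mk) sum_{C != class(S)} P(C)/(1-P(class(S))) sum_j diff(N,S,M_j)
# with diff = |s1 - s2| / range(N) on the raw features, nearest neighbours
# by Euclidean distance on max-min-normalised values, ties to lowest index,
# every instance sampled once.
oracleReliefF <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  y <- as.character(y)
  rng <- apply(X, 2, max) - apply(X, 2, min)
  Z <- X
  for (j in seq_len(p))
    Z[, j] <- if (rng[j] > 0) (X[, j] - min(X[, j])) / rng[j] else 0
  dmat <- matrix(0, n, n)
  for (a in 1:n) for (b in 1:n)
    dmat[a, b] <- sqrt(sum((Z[a, ] - Z[b, ])^2))
  classes <- sort(unique(y))
  priors <- sapply(classes, function(cl) mean(y == cl))
  dfeat <- function(j, a, b)
    if (rng[j] > 0) abs(X[a, j] - X[b, j]) / rng[j] else 0
  W <- numeric(p)
  for (s in 1:n) {
    same <- setdiff(which(y == y[s]), s)
    hits <- same[order(dmat[s, same], same)][1:k]
    for (j in 1:p) for (h in hits)
      W[j] <- W[j] - dfeat(j, s, h) / (n * k)
    for (cl in setdiff(classes, y[s])) {
      others <- which(y == cl)
      misses <- others[order(dmat[s, others], others)][1:k]
      coef <- priors[[cl]] / (1 - priors[[y[s]]])
      for (j in 1:p) for (ms in misses)
        W[j] <- W[j] + coef * dfeat(j, s, ms) / (n * k)
    }
  }
  W
}

# One-sided spectrum total power should match time-domain mean square
# (Parseval); used as the periodogram oracle.
oracleMeanSquare <- function(x) mean((x - mean(x))^2)
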