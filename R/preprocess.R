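# Signal conditioning and quality control: zero-phase Butterworth filtering,
# cubic-spline upsampling of the IMU to the EMG rate, paired windowing,
# stratified 7:1:2 splitting, and the cycle-repeatability statistics.

# Zero-phase filtering with odd-reflection edge padding, so filter-state
# transients decay inside the discarded pad rather than inside the signal.
.zeroPhase <- function(bf, x, padlen = 1024L) {
  n <- length(x)
  p <- min(n - 1L, padlen)
  pre <- 2 * x[1] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth band-pass for EMG
#'
#' 4th-order Butterworth applied forward-backward (zero phase), passing
#' 20--500 Hz by default — the band in which surface-EMG power concentrates.
#'
#' @param x Numeric vector sampled at \code{rate} Hz.
#' @param low,high Band edges in Hz.
#' @param order Filter order (applied twice by filtering both directions).
#' @param rate Sampling rate, default 2000 Hz.
#' @return Filtered vector, same length as \code{x}.
#' @export
bandpassEMG <- function(x, low = 20, high = 500, order = 4, rate = 2000) {
  nyq <- rate / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("high cutoff must be below the Nyquist frequency (",
                        nyq, " Hz)")
  if (length(x) <= 3 * order)
    stop("signal too short for order-", order, " filtering")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  .zeroPhase(bf, as.numeric(x))
}

#' Zero-phase Butterworth low-pass for IMU
#'
#' @param x Numeric vector sampled at \code{rate} Hz (native IMU rate).
#' @param cutoff Cut-off in Hz (default 10).
#' @param order Filter order.
#' @param rate Sampling rate, default 200 Hz.
#' @return Filtered vector, same length as \code{x}.
#' @export
lowpassIMU <- function(x, cutoff = 10, order = 4, rate = 200) {
  nyq <- rate / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency (",
                          nyq, " Hz)")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(x) <= 3 * order)
    stop("signal too short for order-", order, " filtering")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  .zeroPhase(bf, as.numeric(x))
}

#' Squared-magnitude response of the designed zero-phase filters
#'
#' Analytic power gain of [bandpassEMG()] / [lowpassIMU()] at given
#' frequencies.  Because the filters run forward and backward, the amplitude
#' gain is the squared magnitude of the one-pass Butterworth response.
#'
#' @param f Frequencies in Hz.
#' @param type "pass" (EMG band-pass) or "low" (IMU low-pass).
#' @param low,high,cutoff,order,rate Filter parameters as in the filter
#'   functions.
#' @return Amplitude gain (after the two passes) at each frequency.
#' @export
filterGain <- function(f, type = c("pass", "low"), low = 20, high = 500,
                       cutoff = 10, order = 4, rate = 2000) {
  type <- match.arg(type)
  nyq <- rate / 2
  bf <- if (type == "pass")
    signal::butter(order, c(low, high) / nyq, type = "pass")
  else signal::butter(order, cutoff / nyq, type = "low")
  z <- exp(-1i * pi * f / nyq)
  ev <- function(coef) vapply(z, function(zz)
    sum(coef * zz^(seq_along(coef) - 1)), complex(1))
  Mod(ev(bf$b) / ev(bf$a))^2   # filtfilt applies the filter twice
}

#' Cubic-spline upsampling
#'
#' Interpolates a series to an integer multiple of its sampling rate with a
#' cubic spline that passes through every original sample; used to raise the
#' IMU from 200 Hz to the 2000 Hz EMG rate.
#'
#' @param x Numeric vector at \code{rateIn} Hz.
#' @param rateIn,rateOut Input and output rates; \code{rateOut} must be an
#'   integer multiple of \code{rateIn}.
#' @return Vector of length \code{length(x) * rateOut / rateIn}.
#' @examples
#' length(resampleCubic(sin(1:200 / 10), 200, 2000))
#' @export
resampleCubic <- function(x, rateIn = 200, rateOut = 2000) {
  r <- rateOut / rateIn
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop("rateOut must be an integer multiple of rateIn (only upsampling ",
         "is supported)")
  r <- as.integer(round(r))
  n <- length(x)
  if (n < 4) stop("need at least 4 samples for cubic-spline interpolation")
  tin <- (seq_len(n) - 1) / rateIn
  tout <- (seq_len(n * r) - 1) / rateOut
  stats::spline(tin, x, xout = tout, method = "fmm")$y
}

#' Filter a recording and upsample the IMU
#'
#' Applies the EMG band-pass at the native 2000 Hz and the IMU low-pass at
#' the native 200 Hz, then cubic-spline-upsamples the IMU to 2000 Hz so both
#' modalities share one time base.  Filtering precedes resampling so that
#' interpolation cannot re-introduce high-frequency noise.
#'
#' @param bundle A \linkS4class{RecordingBundle}.
#' @param emgBand EMG pass band in Hz.
#' @param imuCutoff IMU low-pass cut-off in Hz.
#' @param order Butterworth order for both filters.
#' @return List with elements \code{emg} (4 x T) and \code{imu} (3 x T), both
#'   at 2000 Hz.
#' @export
conditionRecording <- function(bundle, emgBand = c(20, 500), imuCutoff = 10,
                               order = 4) {
  stopifnot(is(bundle, "RecordingBundle"))
  emgF <- t(apply(bundle@emg, 1, bandpassEMG, low = emgBand[1],
                  high = emgBand[2], order = order, rate = bundle@rateEMG))
  imuF <- t(apply(bundle@imu, 1, function(ch)
    resampleCubic(lowpassIMU(ch, cutoff = imuCutoff, order = order,
                             rate = bundle@rateIMU),
                  bundle@rateIMU, bundle@rateEMG)))
  rownames(emgF) <- rownames(bundle@emg)
  rownames(imuF) <- rownames(bundle@imu)
  list(emg = emgF, imu = imuF)
}

# Cut paired windows out of aligned 2000 Hz matrices; returns NULL-free list
# of index vectors.
.windowStarts <- function(n, window, stride) {
  if (n < window) stop("recording shorter than one window (", n, " < ",
                       window, " samples)")
  seq(0L, n - window, by = stride)
}

#' Segment recordings into paired fixed-length windows
#'
#' Conditions each recording ([conditionRecording()]), trims filter edge
#' transients, and cuts non-overlapping (by default) paired EMG/IMU windows
#' of 600 samples (0.3 s at 2000 Hz) — the network input size.
#'
#' @param bundles List of \linkS4class{RecordingBundle} objects (or a single
#'   bundle).
#' @param window Window length in samples (600).
#' @param stride Step between window starts in samples (default = window,
#'   i.e. non-overlapping).
#' @param trim Seconds trimmed from each end after zero-phase filtering.
#' @param emgBand,imuCutoff,order Passed to [conditionRecording()].
#' @return A \linkS4class{WindowSet} with split "unassigned".
#' @export
buildWindowSet <- function(bundles, window = 600L, stride = window,
                           trim = 0.25, emgBand = c(20, 500), imuCutoff = 10,
                           order = 4) {
  if (is(bundles, "RecordingBundle")) bundles <- list(bundles)
  stopifnot(length(bundles) > 0, window >= 1L, stride >= 1L)
  emgL <- list(); imuL <- list()
  lab <- character(); src <- character(); subj <- character()
  start <- integer()
  for (b in bundles) {
    cond <- conditionRecording(b, emgBand = emgBand, imuCutoff = imuCutoff,
                               order = order)
    nTrim <- round(trim * b@rateEMG)
    keep <- seq(nTrim + 1L, ncol(cond$emg) - nTrim)
    e <- cond$emg[, keep, drop = FALSE]
    im <- cond$imu[, keep, drop = FALSE]
    starts <- .windowStarts(ncol(e), window, stride)
    sid <- if (!is.null(b@meta$sourceId)) b@meta$sourceId
           else sprintf("%s_seed%s", b@mode, b@meta$seed)
    sj <- if (!is.null(b@meta$subject)) b@meta$subject else "S1"
    for (s in starts) {
      emgL[[length(emgL) + 1L]] <- e[, (s + 1L):(s + window)]
      imuL[[length(imuL) + 1L]] <- im[, (s + 1L):(s + window)]
    }
    lab <- c(lab, rep(b@mode, length(starts)))
    src <- c(src, rep(sid, length(starts)))
    subj <- c(subj, rep(sj, length(starts)))
    start <- c(start, as.integer(starts))
  }
  n <- length(emgL)
  emgA <- array(0, c(n, 4L, window))
  imuA <- array(0, c(n, 3L, window))
  for (i in seq_len(n)) { emgA[i, , ] <- emgL[[i]]; imuA[i, , ] <- imuL[[i]] }
  new("WindowSet", emg = emgA, imu = imuA,
      label = factor(lab, levels = .modeLevels),
      split = factor(rep("unassigned", n),
                     levels = c("train", "val", "test", "unassigned")),
      sourceId = src, subject = subj, startIndex = start)
}

#' Assign a stratified train/val/test split
#'
#' Splits window pairs 7:1:2 (by default), stratified by motion mode with
#' largest-remainder rounding, deterministic given the seed.
#'
#' @param ws A \linkS4class{WindowSet}.
#' @param ratio Numeric length-3 ratio (train, val, test).
#' @param seed Integer seed for the within-stratum shuffle.
#' @param byRecording If TRUE, whole recordings (sourceId) are assigned to a
#'   single split instead of individual windows.
#' @return The \linkS4class{WindowSet} with its split slot filled.
#' @export
assignSplit <- function(ws, ratio = c(7, 1, 2), seed = 1L,
                        byRecording = FALSE) {
  stopifnot(is(ws, "WindowSet"), length(ratio) == 3, all(ratio >= 0))
  n <- nWindows(ws)
  if (n < 10L) stop("need at least 10 window pairs to split")
  frac <- ratio / sum(ratio)
  units <- if (byRecording) ws@sourceId else as.character(seq_len(n))
  uLab <- ws@label[!duplicated(units)]
  uIds <- units[!duplicated(units)]
  strata <- levels(droplevels(uLab))
  nPer <- vapply(strata, function(m) sum(uLab == m), integer(1))
  # per-stratum floors, then largest-remainder distribution of the leftover
  # units constrained by the exact global targets, so stratum fractions stay
  # within one unit of the ratio and the overall counts match it exactly
  gTarget <- floor(frac * length(uIds))
  gRem <- frac * length(uIds) - gTarget
  for (extra in order(gRem, decreasing = TRUE))
    if (sum(gTarget) < length(uIds)) gTarget[extra] <- gTarget[extra] + 1L
  base <- vapply(strata, function(m) floor(frac * sum(uLab == m)),
                 numeric(3))
  counts <- t(base)                      # strata x splits
  deficit <- gTarget - colSums(counts)
  for (si in seq_along(strata)) {
    left <- nPer[si] - sum(counts[si, ])
    rem <- frac * nPer[si] - base[, si]
    for (u in seq_len(left)) {
      open <- which(deficit > 0)
      pick <- open[order(rem[open], decreasing = TRUE)][1]
      counts[si, pick] <- counts[si, pick] + 1L
      deficit[pick] <- deficit[pick] - 1L
    }
  }
  assign <- setNames(rep("train", length(uIds)), uIds)
  .withSeed(seed, {
    for (si in seq_along(strata)) {
      ids <- sample(uIds[uLab == strata[si]])
      assign[ids] <- rep(c("train", "val", "test"), times = counts[si, ])
    }
  })
  ws@split <- factor(assign[units],
                     levels = c("train", "val", "test", "unassigned"))
  validObject(ws)
  ws
}

#' Integrated EMG
#'
#' Sum of rectified sample amplitudes over a cycle (or any segment) — the
#' classical muscle-activation intensity summary.
#'
#' @param x Numeric vector.
#' @return Scalar \code{sum(abs(x))}.
#' @examples
#' iemg(c(1, -2, 3))   # 6
#' @export
iemg <- function(x) {
  if (length(x) == 0L) stop("empty input")
  sum(abs(x))
}

#' Pairwise Pearson similarity between cycles
#'
#' @param cycles List of equal-length numeric vectors (>= 2 cycles, length
#'   >= 3, none constant), or a matrix with one cycle per column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
cycleSimilarity <- function(cycles) {
  if (is.list(cycles)) {
    lens <- lengths(cycles)
    if (length(unique(lens)) != 1L) stop("cycles must have equal length")
    cycles <- do.call(cbind, cycles)
  }
  if (ncol(cycles) < 2L) stop("need at least 2 cycles")
  if (nrow(cycles) < 3L) stop("cycles must have length >= 3")
  sds <- apply(cycles, 2, sd)
  if (any(sds == 0)) stop("constant cycle: Pearson correlation undefined")
  stats::cor(cycles)
}

#' Extract normalised gait cycles from a periodic signal
#'
#' Detects cycle boundaries as rising zero crossings of the mean-removed
#' signal (with a minimum-spacing guard against noise-induced crossings) and
#' linearly resamples each cycle to a common length.
#'
#' @param x Numeric vector (typically the IMU angle channel).
#' @param nOut Samples per normalised cycle.
#' @param minSpacingFrac Crossings closer than this fraction of the median
#'   spacing are discarded.
#' @return List with \code{cycles} (nOut x nCycles matrix) and
#'   \code{bounds} (crossing sample indices).
#' @export
extractCycles <- function(x, nOut = 200L, minSpacingFrac = 0.5) {
  xc <- x - mean(x)
  up <- which(xc[-length(xc)] < 0 & xc[-1] >= 0)
  if (length(up) >= 3L) {
    med <- median(diff(up))
    keep <- c(TRUE, diff(up) >= minSpacingFrac * med)
    while (!all(keep)) {
      up <- up[keep]
      if (length(up) < 3L) break
      keep <- c(TRUE, diff(up) >= minSpacingFrac * median(diff(up)))
    }
  }
  if (length(up) < 3L) stop("fewer than two full cycles detected")
  nc <- length(up) - 1L
  cyc <- matrix(0, nOut, nc)
  for (k in seq_len(nc)) {
    seg <- x[up[k]:(up[k + 1L] - 1L)]
    cyc[, k] <- approx(seq_along(seg), seg, n = nOut)$y
  }
  list(cycles = cyc, bounds = up)
}

#' Repeatability quality-control report
#'
#' Reproduces the repeatability check applied to real recordings: Pearson
#' similarity between randomly sampled normalised cycles of each IMU channel
#' (cycle boundaries from the angle channel), and mean +/- SD of per-cycle
#' integrated EMG for each muscle.
#'
#' @param bundle A \linkS4class{RecordingBundle}.
#' @param nCycles Cycles sampled for the similarity matrices (default 5).
#' @param seed Seed for the cycle sample.
#' @param simThreshold Minimum acceptable mean pairwise similarity.
#' @return A \linkS4class{QCReport}.
#' @export
qcReport <- function(bundle, nCycles = 5L, seed = 1L, simThreshold = 0.85) {
  stopifnot(is(bundle, "RecordingBundle"))
  angle <- lowpassIMU(bundle@imu["angle_y", ], rate = bundle@rateIMU)
  bounds <- extractCycles(angle)$bounds
  nc <- length(bounds) - 1L
  pick <- .withSeed(seed, sort(sample(seq_len(nc), min(nCycles, nc))))
  sims <- list()
  for (ch in rownames(bundle@imu)) {
    sig <- lowpassIMU(bundle@imu[ch, ], rate = bundle@rateIMU)
    cyc <- matrix(0, 200L, length(pick))
    for (i in seq_along(pick)) {
      seg <- sig[bounds[pick[i]]:(bounds[pick[i] + 1L] - 1L)]
      cyc[, i] <- approx(seq_along(seg), seg, n = 200L)$y
    }
    sims[[ch]] <- cycleSimilarity(cyc)
  }
  # per-cycle iEMG on the band-passed EMG, cycle bounds mapped to 2000 Hz
  bE <- (bounds - 1L) * (bundle@rateEMG / bundle@rateIMU) + 1L
  stats <- data.frame(muscle = rownames(bundle@emg), mean = NA_real_,
                      sd = NA_real_)
  for (mi in seq_len(nrow(bundle@emg))) {
    sig <- bandpassEMG(bundle@emg[mi, ], rate = bundle@rateEMG)
    vals <- vapply(seq_len(nc), function(k)
      iemg(sig[bE[k]:(bE[k + 1L] - 1L)]), numeric(1))
    stats$mean[mi] <- mean(vals)
    stats$sd[mi] <- sd(vals)
  }
  msim <- vapply(sims, function(m) mean(m[upper.tri(m)]), numeric(1))
  flags <- c(similarity = all(msim >= simThreshold))
  new("QCReport", similarity = sims, iemgStats = stats, passFlags = flags,
      thresholds = list(similarity = simThreshold))
}
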