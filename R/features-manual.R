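# Classical time- and frequency-domain EMG/IMU features, implemented exactly
# as the field defines them: MAV, VAR (uncentred, /(N-1)), RMS, thresholded
# zero crossings, Willison amplitude, waveform length, and the spectral pair
# MDF/MNP on a Parseval-consistent one-sided periodogram.

#' Mean absolute value
#' @param x Numeric vector.
#' @return \code{mean(abs(x))}.
#' @examples mav(c(-1, 2, -3))   # 2
#' @export
mav <- function(x) {
  if (length(x) == 0L) stop("empty input")
  mean(abs(x))
}

#' Signal variance (uncentred)
#'
#' The EMG "VAR" feature: \code{sum(x^2) / (N - 1)} with no mean subtraction
#' — for a zero-mean signal this is the conventional variance, but the
#' feature is defined directly on the raw samples.
#'
#' @param x Numeric vector, length >= 2.
#' @return Scalar.
#' @examples sigVar(c(1, -1))   # 2
#' @export
sigVar <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  sum(x^2) / (n - 1)
}

#' Root mean square
#' @param x Numeric vector.
#' @return \code{sqrt(mean(x^2))}; always >= [mav()].
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("empty input")
  sqrt(mean(x^2))
}

#' Thresholded zero-crossing count
#'
#' Counts sample pairs that change sign with an amplitude step larger than
#' the noise-rejection threshold \code{delta}: positions i where
#' \code{x[i] * x[i+1] < 0} and \code{|x[i] - x[i+1]| > delta}.
#'
#' @param x Numeric vector, length >= 2.
#' @param delta Amplitude threshold (same units as x), >= 0.
#' @return Integer count.
#' @examples zc(c(1, -1, 1, -1), 0.5)   # 3
#' @export
zc <- function(x, delta = 0) {
  if (length(x) < 2L) stop("need at least 2 samples")
  stopifnot(delta >= 0)
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) > delta)
}

#' Willison amplitude
#'
#' Counts consecutive-sample amplitude steps reaching the threshold:
#' positions i with \code{|x[i] - x[i+1]| >= threshold}.
#'
#' @param x Numeric vector, length >= 2.
#' @param threshold Amplitude threshold, >= 0.
#' @return Integer count.
#' @examples wamp(c(0, 1, 0), 0.5)   # 2
#' @export
wamp <- function(x, threshold = 0) {
  if (length(x) < 2L) stop("need at least 2 samples")
  stopifnot(threshold >= 0)
  sum(abs(diff(x)) >= threshold)
}

#' Waveform length
#' @param x Numeric vector, length >= 2.
#' @return \code{sum(abs(diff(x)))}.
#' @examples wl(c(0, 1, 0))   # 2
#' @export
wl <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  sum(abs(diff(x)))
}

#' One-sided periodogram
#'
#' Mean-removed, Parseval-consistent power spectrum: the bin powers sum to
#' the mean square of the mean-removed signal.  DC is excluded; bins run
#' from rate/N up to the Nyquist frequency.
#'
#' @param x Numeric vector, length >= 8.
#' @param rate Sampling rate in Hz.
#' @return List with \code{frequency} (Hz) and \code{power} (one-sided bin
#'   powers), plus \code{M} (number of bins).
#' @export
powerSpectrum <- function(x, rate) {
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples")
  xc <- x - mean(x)
  p <- Mod(fft(xc))^2 / n^2
  half <- floor(n / 2)
  idx <- 2:(half + 1)                    # drop DC, keep up to Nyquist
  pow <- p[idx]
  dbl <- if (n %% 2 == 0) idx[-length(idx)] else idx  # interior bins
  pow[seq_along(dbl)] <- 2 * p[dbl]
  if (n %% 2 == 0) pow[length(pow)] <- p[half + 1]
  list(frequency = (seq_len(half)) * rate / n, power = pow, M = half)
}

#' Median frequency
#'
#' The smallest frequency bin at which cumulative power reaches half the
#' total — the frequency splitting spectral power in two equal halves.
#'
#' @param spec A spectrum from [powerSpectrum()].
#' @return Frequency in Hz.
#' @export
mdf <- function(spec) {
  tot <- sum(spec$power)
  if (tot <= 0) stop("total power must be positive")
  spec$frequency[which(cumsum(spec$power) >= tot / 2)[1]]
}

#' Mean power
#' @param spec A spectrum from [powerSpectrum()].
#' @return Mean per-bin power \code{sum(p)/M}.
#' @export
mnp <- function(spec) {
  if (spec$M < 1L) stop("empty spectrum")
  sum(spec$power) / spec$M
}

.EMG_FEATURES <- c("MAV", "VAR", "RMS", "WAMP", "ZC", "WL", "MDF", "MNP")
.IMU_FEATURES <- c("MAV", "VAR", "RMS", "ZC", "MDF", "MNP")
.TIME_FEATURES <- c("MAV", "VAR", "RMS", "WAMP", "ZC", "WL")
.FREQ_FEATURES <- c("MDF", "MNP")

.computeFeature <- function(name, x, rate, zcFrac, wampFrac, spec = NULL) {
  switch(name,
         MAV = mav(x),
         VAR = sigVar(x),
         RMS = rms(x),
         ZC = zc(x, delta = zcFrac * rms(x)),
         WAMP = wamp(x, threshold = wampFrac * rms(x)),
         WL = wl(x),
         MDF = mdf(spec),
         MNP = mnp(spec),
         stop("unknown feature '", name, "'"))
}

#' Construct a MotionFeatures container
#'
#' @param values Windows x features numeric matrix.
#' @param modality Character per feature ("emg", "imu" or "cnn").
#' @param label,split,subject Per-window annotations.
#' @return A \linkS4class{MotionFeatures}.
#' @export
MotionFeatures <- function(values, modality, label,
                           split = factor(rep("unassigned", nrow(values)),
                                          levels = c("train", "val", "test",
                                                     "unassigned")),
                           subject = rep(NA_character_, nrow(values))) {
  stopifnot(is.matrix(values), !anyNA(values),
            length(modality) == ncol(values))
  se <- SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = S4Vectors::DataFrame(modality = modality,
                                   row.names = colnames(values)),
    colData = S4Vectors::DataFrame(label = as.character(label), split = split,
                                   subject = subject))
  new("MotionFeatures", se)
}

#' Extract the manual feature bank from a WindowSet
#'
#' Per window and channel: the EMG feature set
#' \{MAV, VAR, RMS, WAMP, ZC, WL, MDF, MNP\} over the four muscles and the
#' IMU set \{MAV, VAR, RMS, ZC, MDF, MNP\} over the three kinematic
#' channels.  ZC and WAMP thresholds default to fixed fractions of each
#' window-channel RMS so counts stay meaningful across arbitrary units.
#'
#' @param ws A \linkS4class{WindowSet}.
#' @param emgFeatures,imuFeatures Feature name subsets.
#' @param zcFrac,wampFrac Threshold fractions of window-channel RMS.
#' @param rate Sampling rate of the windows (2000 Hz).
#' @return A \linkS4class{MotionFeatures}; columns ordered channel-major
#'   (EMG channels first), named \code{<modality>_<channel>_<feature>}.
#' @export
extractManualFeatures <- function(ws, emgFeatures = .EMG_FEATURES,
                                  imuFeatures = .IMU_FEATURES,
                                  zcFrac = 0.01, wampFrac = 0.05,
                                  rate = 2000) {
  stopifnot(is(ws, "WindowSet"), nWindows(ws) > 0)
  bad <- setdiff(c(emgFeatures, imuFeatures), .EMG_FEATURES)
  if (length(bad)) stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  emgCh <- .MUSCLES
  imuCh <- .IMU_CHANNELS
  cn <- c(if (length(emgFeatures))
            as.vector(t(outer(emgCh, emgFeatures,
                              function(a, b) paste("emg", a, b, sep = "_")))),
          if (length(imuFeatures))
            as.vector(t(outer(imuCh, imuFeatures,
                              function(a, b) paste("imu", a, b, sep = "_")))))
  n <- nWindows(ws)
  vals <- matrix(0, n, length(cn), dimnames = list(NULL, cn))
  for (i in seq_len(n)) {
    col <- 0L
    for (ci in seq_along(emgCh)) {
      x <- ws@emg[i, ci, ]
      spec <- if (any(emgFeatures %in% .FREQ_FEATURES))
        powerSpectrum(x, rate) else NULL
      for (f in emgFeatures) {
        col <- col + 1L
        vals[i, col] <- .computeFeature(f, x, rate, zcFrac, wampFrac, spec)
      }
    }
    for (ci in seq_along(imuCh)) {
      x <- ws@imu[i, ci, ]
      spec <- if (any(imuFeatures %in% .FREQ_FEATURES))
        powerSpectrum(x, rate) else NULL
      for (f in imuFeatures) {
        col <- col + 1L
        vals[i, col] <- .computeFeature(f, x, rate, zcFrac, wampFrac, spec)
      }
    }
  }
  modality <- c(rep("emg", length(emgCh) * length(emgFeatures)),
                rep("imu", length(imuCh) * length(imuFeatures)))
  MotionFeatures(vals, modality, ws@label, ws@split, ws@subject)
}

# Condition-code -> feature subset mapping for the manual comparison grid.
.manualConditionSets <- function(code) {
  base <- switch(code,
    ITD = list(emg = character(), imu = c("MAV", "VAR", "RMS", "ZC")),
    IFD = list(emg = character(), imu = .FREQ_FEATURES),
    ITF = list(emg = character(), imu = .IMU_FEATURES),
    ETD = list(emg = .TIME_FEATURES, imu = character()),
    EFD = list(emg = .FREQ_FEATURES, imu = character()),
    ETF = list(emg = .EMG_FEATURES, imu = character()),
    stop("unknown manual condition '", code, "'"))
  base
}

#' Manual features for a named comparison condition
#'
#' Maps the condition codes of the comparison grid (ITD, IFD, ITF for IMU
#' time/frequency/both; ETD, EFD, ETF for EMG; "+"-joined codes for their
#' fusion, e.g. "ETF+ITF") to the corresponding feature subset.
#'
#' @param ws A \linkS4class{WindowSet}.
#' @param condition Condition code.
#' @param ... Passed to [extractManualFeatures()].
#' @return A \linkS4class{MotionFeatures}.
#' @export
manualCondition <- function(ws, condition, ...) {
  parts <- strsplit(condition, "+", fixed = TRUE)[[1]]
  emgSet <- character(); imuSet <- character()
  for (p in parts) {
    s <- .manualConditionSets(p)
    emgSet <- union(emgSet, s$emg)
    imuSet <- union(imuSet, s$imu)
  }
  extractManualFeatures(ws, emgFeatures = emgSet, imuFeatures = imuSet, ...)
}
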