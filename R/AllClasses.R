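#' Gait generator parameters
#'
#' Parameter set controlling the synthetic gait-signal generator for one
#' motion mode.  EMG is modelled as per-muscle Gaussian activation envelopes
#' (in cycle-phase units) multiplying a band-limited Gaussian carrier; IMU
#' channels are two-harmonic Fourier series of the (jittered) cycle phase.
#'
#' @slot cadence Cycle frequency in Hz.
#' @slot muscleEnvelopes Named list (RF, TA, BF, GA); each element a
#'   data.frame with columns \code{center} (phase in [0,1)), \code{width}
#'   (phase units, > 0) and \code{amplitude} (arbitrary EMG units).
#' @slot imuHarmonics Named list (acc_y, gyro_y, angle_y); each element a list
#'   with \code{offset}, \code{amp} (length 2) and \code{phase} (length 2,
#'   radians) for the first two cadence harmonics.
#' @slot cycleJitter Relative SD of the per-cycle period perturbation
#'   (dimensionless, >= 0).  Also scales a smooth within-cycle phase wobble.
#' @slot emgNoiseFloor Additive white-noise SD on EMG (same units as the
#'   envelopes).
#' @slot imuNoiseSD Additive noise SD per IMU channel (g, deg/s, deg).
#' @slot emgBand Carrier pass band in Hz, default c(20, 500); must lie inside
#'   (0, 1000), i.e. below the EMG Nyquist frequency.
#' @seealso [defaultGaitParams()]
#' @export
setClass("GaitParams", representation(
  cadence = "numeric",
  muscleEnvelopes = "list",
  imuHarmonics = "list",
  cycleJitter = "numeric",
  emgNoiseFloor = "numeric",
  imuNoiseSD = "numeric",
  emgBand = "numeric"
))

setValidity("GaitParams", function(object) {
  msg <- character()
  if (length(object@cadence) != 1L || !is.finite(object@cadence) ||
      object@cadence <= 0)
    msg <- c(msg, "cadence must be a single positive number")
  if (!identical(sort(names(object@muscleEnvelopes)),
                 sort(c("RF", "TA", "BF", "GA"))))
    msg <- c(msg, "muscleEnvelopes must be named RF, TA, BF, GA")
  for (nm in names(object@muscleEnvelopes)) {
    env <- object@muscleEnvelopes[[nm]]
    if (!all(c("center", "width", "amplitude") %in% names(env)))
      msg <- c(msg, sprintf("envelope '%s' lacks center/width/amplitude", nm))
    else if (any(env$width <= 0))
      msg <- c(msg, sprintf("envelope '%s' has non-positive width", nm))
  }
  if (!identical(sort(names(object@imuHarmonics)),
                 sort(c("acc_y", "gyro_y", "angle_y"))))
    msg <- c(msg, "imuHarmonics must be named acc_y, gyro_y, angle_y")
  if (object@cycleJitter < 0) msg <- c(msg, "cycleJitter must be >= 0")
  if (length(object@emgBand) != 2L || object@emgBand[1] <= 0 ||
      object@emgBand[2] <= object@emgBand[1] || object@emgBand[2] >= 1000)
    msg <- c(msg, "emgBand must satisfy 0 < low < high < 1000 Hz")
  if (length(object@imuNoiseSD) != 3L || any(object@imuNoiseSD < 0))
    msg <- c(msg, "imuNoiseSD must be three non-negative values")
  if (length(msg)) msg else TRUE
})

#' Synthetic subject profile
#'
#' Multiplicative per-muscle amplitude and cadence scalings plus a seed
#' offset, standing in for between-subject variability.
#'
#' @slot subjectId Identifier, e.g. "S1".
#' @slot amplitudeScale Named numeric (RF, TA, BF, GA), all > 0.
#' @slot cadenceScale Single positive multiplier.
#' @slot seedOffset Integer mixed into per-recording seeds.
#' @seealso [defaultSubjectProfiles()]
#' @export
setClass("SubjectProfile", representation(
  subjectId = "character",
  amplitudeScale = "numeric",
  cadenceScale = "numeric",
  seedOffset = "integer"
))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (any(object@amplitudeScale <= 0) || object@cadenceScale <= 0)
    msg <- c(msg, "scales must be positive")
  if (length(msg)) msg else TRUE
})

#' Paired EMG + IMU recording
#'
#' One labelled recording: 4-channel surface EMG at 2000 Hz and 3-channel IMU
#' (acceleration, angular velocity, angle about the sensor Y axis) at 200 Hz,
#' covering the same time span.
#'
#' @slot emg 4 x T numeric matrix (rows RF, TA, BF, GA), arbitrary EMG units.
#' @slot imu 3 x T' numeric matrix (rows acc_y [g], gyro_y [deg/s],
#'   angle_y [deg]).
#' @slot mode One of [motionModes()].
#' @slot duration Seconds.
#' @slot rateEMG,rateIMU Sampling rates in Hz (2000 and 200 by default).
#' @slot meta List of provenance (seed, subject, generator parameters, ...).
#' @export
setClass("RecordingBundle", representation(
  emg = "matrix",
  imu = "matrix",
  mode = "character",
  duration = "numeric",
  rateEMG = "numeric",
  rateIMU = "numeric",
  meta = "list"
))

setValidity("RecordingBundle", function(object) {
  msg <- character()
  if (nrow(object@emg) != 4L) msg <- c(msg, "emg must have 4 rows")
  if (nrow(object@imu) != 3L) msg <- c(msg, "imu must have 3 rows")
  if (!object@mode %in% .modeLevels)
    msg <- c(msg, "mode must be one of motionModes()")
  tE <- round(object@duration * object@rateEMG)
  tI <- round(object@duration * object@rateIMU)
  if (ncol(object@emg) != tE)
    msg <- c(msg, sprintf("emg has %d samples, expected %d", ncol(object@emg), tE))
  if (ncol(object@imu) != tI)
    msg <- c(msg, sprintf("imu has %d samples, expected %d", ncol(object@imu), tI))
  if (anyNA(object@emg) || anyNA(object@imu))
    msg <- c(msg, "missing values are not allowed")
  if (length(msg)) msg else TRUE
})

#' Paired, aligned windows of EMG and IMU data
#'
#' Fixed-length (channels x 600) segments cut from filtered recordings after
#' the IMU has been upsampled to the EMG rate, so paired EMG and IMU windows
#' with the same start index cover the same 0.3 s of movement.
#'
#' @slot emg N x 4 x 600 array.
#' @slot imu N x 3 x 600 array.
#' @slot label Factor over [motionModes()] levels, one per pair.
#' @slot split Factor with levels train/val/test/unassigned.
#' @slot sourceId Recording identifier per pair.
#' @slot subject Subject identifier per pair.
#' @slot startIndex 0-based sample offset of each window in its recording.
#' @seealso [buildWindowSet()], [assignSplit()]
#' @export
setClass("WindowSet", representation(
  emg = "array",
  imu = "array",
  label = "factor",
  split = "factor",
  sourceId = "character",
  subject = "character",
  startIndex = "integer"
))

setValidity("WindowSet", function(object) {
  msg <- character()
  dE <- dim(object@emg); dI <- dim(object@imu)
  if (length(dE) != 3L || dE[2] != 4L || dE[3] != 600L)
    msg <- c(msg, "emg must be N x 4 x 600")
  if (length(dI) != 3L || dI[2] != 3L || dI[3] != 600L)
    msg <- c(msg, "imu must be N x 3 x 600")
  n <- dE[1]
  if (dI[1] != n) msg <- c(msg, "emg and imu window counts differ")
  for (s in c("label", "split", "sourceId", "subject", "startIndex"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' length != number of windows", s))
  if (!all(levels(object@split) == c("train", "val", "test", "unassigned")))
    msg <- c(msg, "split levels must be train/val/test/unassigned")
  if (length(msg)) msg else TRUE
})

#' Quality-control report for a recording
#'
#' Cycle-to-cycle Pearson similarity of sampled IMU cycles and per-muscle
#' mean +/- SD of per-cycle integrated EMG, with pass flags against the
#' configured thresholds.
#'
#' @slot similarity Named list of pairwise Pearson matrices, one per IMU
#'   channel.
#' @slot iemgStats data.frame with columns muscle, mean, sd.
#' @slot passFlags Named logical vector.
#' @slot thresholds List of thresholds used.
#' @seealso [qcReport()]
#' @export
setClass("QCReport", representation(
  similarity = "list",
  iemgStats = "data.frame",
  passFlags = "logical",
  thresholds = "list"
))

#' Feature matrix container
#'
#' Thin extension of \linkS4class{SummarizedExperiment}: rows are features,
#' columns are windows.  \code{rowData} carries the feature modality
#' ("emg", "imu" or "cnn"); \code{colData} carries the window label, split
#' and subject.  [featureValues()] returns the transposed windows x features
#' matrix most classifiers expect.
#'
#' @seealso [MotionFeatures()], [extractManualFeatures()], [extractFeatures()]
#' @export
setClass("MotionFeatures", contains = "SummarizedExperiment")

#' ReliefF weight vector
#'
#' @slot weights Named per-feature weights W(N).
#' @slot kept Integer indices of features with weight >= threshold.
#' @slot threshold Selection cutoff (0.1 by default).
#' @slot priors Class prior proportions P(C) (sum to 1).
#' @slot k Neighbours per class used.
#' @seealso [relieffWeights()], [selectFeatures()]
#' @export
setClass("ReliefFWeights", representation(
  weights = "numeric",
  kept = "integer",
  threshold = "numeric",
  priors = "numeric",
  k = "integer"
))

setValidity("ReliefFWeights", function(object) {
  msg <- character()
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "class priors must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Trained convolutional feature extractor
#'
#' A dual- or single-stream convolutional network trained on labelled window
#' pairs, with its output layer retained for classification but tapped before
#' it for feature extraction.
#'
#' @slot arch One of "dual", "emg", "imu", "fused".
#' @slot spec Architecture description (see [dualStreamSpec()]).
#' @slot params Named list of weight matrices / bias vectors.
#' @slot norm Per-channel normalisation statistics fitted on the training
#'   split (empty until trained).
#' @slot history Per-epoch data.frame: loss, train accuracy, val accuracy.
#' @slot tap Default extraction tap, "fc32" or "fusion320".
#' @slot classLevels Label levels seen at training time.
#' @slot trained Logical.
#' @seealso [buildDualStream()], [trainExtractor()], [extractFeatures()]
#' @export
setClass("TrainedExtractor", representation(
  arch = "character",
  spec = "list",
  params = "list",
  norm = "list",
  history = "data.frame",
  tap = "character",
  classLevels = "character",
  trained = "logical"
))

#' Cross-validation evaluation report
#'
#' @slot condition Condition label (e.g. "IEDL", "ISL", "ETF+ITF").
#' @slot classifier One of "SVM", "KNN", "DT", "RF".
#' @slot foldAccuracy Per-fold held-out accuracies.
#' @slot confusion Confusion matrix summed over folds (rows = truth).
#' @slot seed Seed used for fold assignment and classifier fitting.
#' @seealso [crossValidate()], [runComparison()]
#' @export
setClass("EvaluationReport", representation(
  condition = "character",
  classifier = "character",
  foldAccuracy = "numeric",
  confusion = "matrix",
  seed = "integer"
))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (any(object@foldAccuracy < 0 | object@foldAccuracy > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
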