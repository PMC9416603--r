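#' Accessors for pipeline objects
#'
#' Small accessor family: \code{emg()}/\code{imu()} return the raw signal
#' matrices or window arrays, \code{motionMode()} the recording label,
#' \code{nWindows()} the number of paired windows, \code{windowLabels()},
#' \code{windowSplit()} and \code{windowSubject()} the per-window annotations,
#' \code{featureValues()} the windows x features matrix of a
#' \linkS4class{MotionFeatures} object, \code{featureWeights()} the per-feature
#' ReliefF weights, \code{keptFeatures()} the surviving feature indices,
#' \code{meanAccuracy()} and \code{foldAccuracy()} the accuracies of an
#' \linkS4class{EvaluationReport}, and \code{trainingHistory()} the per-epoch
#' log of a \linkS4class{TrainedExtractor}.
#'
#' @param x An object of the documented class.
#' @return See details; accessors return the slot contents described above.
#' @name accessors
#' @aliases emg imu motionMode nWindows windowLabels windowSplit windowSubject
#'   featureValues featureWeights keptFeatures meanAccuracy foldAccuracy
#'   trainingHistory
NULL

#' @rdname accessors
#' @export
setGeneric("emg", function(x) standardGeneric("emg"))
#' @rdname accessors
#' @export
setGeneric("imu", function(x) standardGeneric("imu"))
#' @rdname accessors
#' @export
setGeneric("motionMode", function(x) standardGeneric("motionMode"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("windowSplit", function(x) standardGeneric("windowSplit"))
#' @rdname accessors
#' @export
setGeneric("windowSubject", function(x) standardGeneric("windowSubject"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))
#' @rdname accessors
#' @export
setGeneric("keptFeatures", function(x) standardGeneric("keptFeatures"))
#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setGeneric("foldAccuracy", function(x) standardGeneric("foldAccuracy"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
setMethod("emg", "RecordingBundle", function(x) x@emg)
#' @rdname accessors
setMethod("imu", "RecordingBundle", function(x) x@imu)
#' @rdname accessors
setMethod("emg", "WindowSet", function(x) x@emg)
#' @rdname accessors
setMethod("imu", "WindowSet", function(x) x@imu)
#' @rdname accessors
setMethod("motionMode", "RecordingBundle", function(x) x@mode)
#' @rdname accessors
setMethod("nWindows", "WindowSet", function(x) dim(x@emg)[1])
#' @rdname accessors
setMethod("windowLabels", "WindowSet", function(x) x@label)
#' @rdname accessors
setMethod("windowSplit", "WindowSet", function(x) x@split)
#' @rdname accessors
setMethod("windowSubject", "WindowSet", function(x) x@subject)
#' @rdname accessors
setMethod("windowLabels", "MotionFeatures",
          function(x) factor(colData(x)$label, levels = .modeLevels))
#' @rdname accessors
setMethod("windowSplit", "MotionFeatures", function(x) colData(x)$split)
#' @rdname accessors
setMethod("windowSubject", "MotionFeatures", function(x) colData(x)$subject)
#' @rdname accessors
setMethod("featureValues", "MotionFeatures", function(x) t(assay(x)))
#' @rdname accessors
setMethod("featureWeights", "ReliefFWeights", function(x) x@weights)
#' @rdname accessors
setMethod("keptFeatures", "ReliefFWeights", function(x) x@kept)
#' @rdname accessors
setMethod("meanAccuracy", "EvaluationReport", function(x) mean(x@foldAccuracy))
#' @rdname accessors
setMethod("foldAccuracy", "EvaluationReport", function(x) x@foldAccuracy)
#' @rdname accessors
setMethod("trainingHistory", "TrainedExtractor", function(x) x@history)

#' Subset a WindowSet
#'
#' @param x A \linkS4class{WindowSet}.
#' @param i Logical or integer index over window pairs.
#' @param j,...,drop Ignored.
#' @return The subsetted \linkS4class{WindowSet}.
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  new("WindowSet",
      emg = x@emg[i, , , drop = FALSE],
      imu = x@imu[i, , , drop = FALSE],
      label = x@label[i],
      split = x@split[i],
      sourceId = x@sourceId[i],
      subject = x@subject[i],
      startIndex = x@startIndex[i])
})

setMethod("show", "RecordingBundle", function(object) {
  cat(sprintf("RecordingBundle: mode=%s, %.1f s (EMG 4 x %d @ %g Hz, IMU 3 x %d @ %g Hz)\n",
              object@mode, object@duration, ncol(object@emg), object@rateEMG,
              ncol(object@imu), object@rateIMU))
})

setMethod("show", "WindowSet", function(object) {
  n <- nWindows(object)
  cat(sprintf("WindowSet: %d paired windows (4 x 600 EMG + 3 x 600 IMU)\n", n))
  if (n) {
    cat("  labels: ")
    print(table(object@label))
    cat("  split:  ")
    print(table(object@split))
  }
})

setMethod("show", "MotionFeatures", function(object) {
  cat(sprintf("MotionFeatures: %d features x %d windows\n",
              nrow(object), ncol(object)))
  mods <- table(rowData(object)$modality)
  cat("  modality:", paste(sprintf("%s=%d", names(mods), mods), collapse = ", "),
      "\n")
})

setMethod("show", "ReliefFWeights", function(object) {
  cat(sprintf("ReliefFWeights: %d features, k=%d, threshold=%g, %d kept\n",
              length(object@weights), object@k, object@threshold,
              length(object@kept)))
})

setMethod("show", "TrainedExtractor", function(object) {
  cat(sprintf("TrainedExtractor: arch=%s, %s, tap=%s\n", object@arch,
              if (object@trained) sprintf("trained %d epochs",
                                          nrow(object@history)) else "untrained",
              object@tap))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %s / %s, mean accuracy %.4f (folds: %s)\n",
              object@condition, object@classifier, meanAccuracy(object),
              paste(sprintf("%.3f", object@foldAccuracy), collapse = " ")))
})

setMethod("show", "QCReport", function(object) {
  sims <- vapply(object@similarity,
                 function(m) mean(m[upper.tri(m)]), numeric(1))
  cat("QCReport\n  mean cycle similarity:",
      paste(sprintf("%s=%.3f", names(sims), sims), collapse = ", "), "\n")
  cat("  pass:", paste(sprintf("%s=%s", names(object@passFlags),
                               object@passFlags), collapse = ", "), "\n")
})
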