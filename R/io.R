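# Text interchange: recordings as paired CSVs + JSON sidecar, feature
# matrices as CSV, window sets as single-file RDS containers.

#' Write / read a recording as delimited text
#'
#' One CSV per modality (\code{<prefix>_emg.csv} with columns
#' time,RF,TA,BF,GA; \code{<prefix>_imu.csv} with time,acc_y,gyro_y,angle_y;
#' time in seconds) plus a JSON sidecar \code{<prefix>_meta.json} with mode,
#' rates, duration and provenance.
#'
#' @param bundle A \linkS4class{RecordingBundle}.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to the recording's sourceId.
#' @return \code{writeRecording} returns the prefix path invisibly;
#'   \code{readRecording} the \linkS4class{RecordingBundle}.
#' @export
writeRecording <- function(bundle, dir, prefix = NULL) {
  stopifnot(is(bundle, "RecordingBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix))
    prefix <- if (!is.null(bundle@meta$sourceId)) bundle@meta$sourceId
              else sprintf("%s_seed%s", bundle@mode, bundle@meta$seed)
  base <- file.path(dir, prefix)
  tE <- (seq_len(ncol(bundle@emg)) - 1) / bundle@rateEMG
  tI <- (seq_len(ncol(bundle@imu)) - 1) / bundle@rateIMU
  data.table::fwrite(data.table::data.table(time = tE, t(bundle@emg)),
                     paste0(base, "_emg.csv"))
  data.table::fwrite(data.table::data.table(time = tI, t(bundle@imu)),
                     paste0(base, "_imu.csv"))
  jsonlite::write_json(
    c(list(mode = bundle@mode, duration = bundle@duration,
           rateEMG = bundle@rateEMG, rateIMU = bundle@rateIMU),
      bundle@meta),
    paste0(base, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @param prefixPath Path prefix as returned by \code{writeRecording} (i.e.
#'   \code{dir/prefix}).
#' @rdname writeRecording
#' @export
readRecording <- function(prefixPath) {
  meta <- jsonlite::read_json(paste0(prefixPath, "_meta.json"),
                              simplifyVector = TRUE)
  emg <- data.table::fread(paste0(prefixPath, "_emg.csv"))
  imu <- data.table::fread(paste0(prefixPath, "_imu.csv"))
  extra <- meta[setdiff(names(meta),
                        c("mode", "duration", "rateEMG", "rateIMU"))]
  new("RecordingBundle",
      emg = t(as.matrix(emg[, -1])), imu = t(as.matrix(imu[, -1])),
      mode = meta$mode, duration = meta$duration,
      rateEMG = meta$rateEMG, rateIMU = meta$rateIMU,
      meta = extra)
}

#' Write / read a feature matrix as CSV
#'
#' Wide CSV: one row per window, feature columns first, then label, split
#' and subject columns — the schema shared by the manual, CNN and selected
#' feature sets.
#'
#' @param feats A \linkS4class{MotionFeatures}.
#' @param path CSV path.
#' @return \code{writeFeatureCSV} returns \code{path} invisibly;
#'   \code{readFeatureCSV} the \linkS4class{MotionFeatures} (modality is
#'   recovered from the column-name prefix).
#' @export
writeFeatureCSV <- function(feats, path) {
  stopifnot(is(feats, "MotionFeatures"))
  df <- data.table::data.table(featureValues(feats))
  df$label <- as.character(windowLabels(feats))
  df$split <- as.character(windowSplit(feats))
  df$subject <- windowSubject(feats)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  ann <- c("label", "split", "subject")
  vals <- as.matrix(df[, setdiff(names(df), ann), drop = FALSE])
  modality <- sub("_.*$", "", colnames(vals))
  modality[!modality %in% c("emg", "imu", "cnn")] <- "cnn"
  MotionFeatures(vals, modality,
                 factor(df$label, levels = .modeLevels),
                 factor(df$split,
                        levels = c("train", "val", "test", "unassigned")),
                 as.character(df$subject))
}

#' Write ReliefF weights as two-column CSV
#'
#' @param wv A \linkS4class{ReliefFWeights}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeWeightsCSV <- function(wv, path) {
  stopifnot(is(wv, "ReliefFWeights"))
  data.table::fwrite(data.table::data.table(
    feature = names(wv@weights), weight = wv@weights), path)
  invisible(path)
}

#' Save / load a WindowSet container
#'
#' Single-file binary container for segmented window sets (arrays
#' N x 4 x 600 and N x 3 x 600 plus labels, splits and provenance).
#'
#' @param ws A \linkS4class{WindowSet}.
#' @param path File path (.rds).
#' @return \code{saveWindowSet} returns \code{path} invisibly;
#'   \code{loadWindowSet} the \linkS4class{WindowSet}.
#' @export
saveWindowSet <- function(ws, path) {
  stopifnot(is(ws, "WindowSet"))
  saveRDS(ws, path)
  invisible(path)
}

#' @rdname saveWindowSet
#' @export
loadWindowSet <- function(path) {
  ws <- readRDS(path)
  stopifnot(is(ws, "WindowSet"))
  ws
}
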