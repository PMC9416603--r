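# End-to-end orchestration: simulate -> preprocess -> train extractor ->
# extract -> ReliefF select -> classify -> report, driven by one nested
# config and one global seed, with a manifest and log in the run directory.

#' Default pipeline configuration
#'
#' Nested configuration mirroring each stage's parameters.  All randomness
#' derives from the single \code{seed}; stage seeds are offset from it
#' deterministically.
#'
#' @param seed Global seed.
#' @return Nested list; edit fields or supply YAML overrides via
#'   [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    data = list(subjects = 6L, modes = motionModes(), repsPerMode = 1L,
                duration = 8),
    preprocess = list(window = 600L, stride = 600L, trim = 0.25,
                      emgBand = c(20, 500), imuCutoff = 10,
                      split = c(7, 1, 2)),
    cnn = list(arch = "dual", epochs = 30L, batchSize = 64L, lr = 1e-3,
               tap = "fusion320"),
    relieff = list(k = 10L, threshold = 0.1),
    classify = list(classifiers = c("SVM", "KNN", "DT", "RF"), folds = 5L)
  )
}

.mergeConfig <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown config key '", paste0(path, nm), "'")
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      .mergeConfig(base[[nm]], override[[nm]], paste0(path, nm, "$"))
    else override[[nm]]
  }
  base
}

.checkConfig <- function(cfg) {
  need <- names(defaultPipelineConfig())
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing section(s): ", paste(miss, collapse = ", "))
  cfg
}

#' Run the full pipeline
#'
#' Generates the synthetic dataset, conditions and windows it, assigns the
#' 7:1:2 split, trains the convolutional extractor, extracts and
#' ReliefF-selects features, benchmarks the classifiers, and writes every
#' stage product (recordings, window container, feature CSVs, weights,
#' reports, per-subject table, 3-D coordinates, resolved config, manifest
#' with checksums) into \code{outDir}.  Re-running with the same config and
#' seed reproduces all outputs.
#'
#' @param config A config list (see [defaultPipelineConfig()]), a YAML file
#'   path, or NULL for the defaults.
#' @param outDir Run directory (created; contents overwritten).
#' @param verbose Log stage progress.
#' @return Invisibly, a list with the window set, extractor, features,
#'   weights, reports, per-subject table and the manifest path.
#' @export
runPipeline <- function(config = NULL, outDir = "dsgait-run",
                        verbose = TRUE) {
  cfg <- defaultPipelineConfig()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- .mergeConfig(cfg, config)
  cfg <- .checkConfig(cfg)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  cat("", file = logFile)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = logFile, append = TRUE)
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage %s: done", name)
    out
  }
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))

  bundles <- stage("simulate", {
    profiles <- defaultSubjectProfiles(cfg$data$subjects)
    b <- generateDataset(profiles, cfg$data$modes, cfg$data$repsPerMode,
                         cfg$data$duration, cfg$seed)
    recDir <- file.path(outDir, "recordings")
    for (x in b) writeRecording(x, recDir)
    say("simulate: %d recordings", length(b))
    b
  })

  ws <- stage("preprocess", {
    w <- buildWindowSet(bundles, window = cfg$preprocess$window,
                        stride = cfg$preprocess$stride,
                        trim = cfg$preprocess$trim,
                        emgBand = cfg$preprocess$emgBand,
                        imuCutoff = cfg$preprocess$imuCutoff)
    w <- assignSplit(w, ratio = cfg$preprocess$split, seed = cfg$seed + 1L)
    saveWindowSet(w, file.path(outDir, "windows.rds"))
    say("preprocess: %d window pairs", nWindows(w))
    w
  })

  manual <- stage("features-manual", {
    f <- extractManualFeatures(ws)
    writeFeatureCSV(f, file.path(outDir, "features_manual.csv"))
    f
  })

  ex <- stage("train-extractor", {
    nCl <- length(unique(cfg$data$modes))
    model <- if (cfg$cnn$arch == "dual")
      buildDualStream(seed = cfg$seed + 2L, nClasses = nCl)
    else buildSingleStream(cfg$cnn$arch, seed = cfg$seed + 2L,
                           nClasses = nCl)
    model <- trainExtractor(model, ws, epochs = cfg$cnn$epochs,
                            batchSize = cfg$cnn$batchSize, lr = cfg$cnn$lr,
                            seed = cfg$seed + 3L)
    saveExtractor(model, file.path(outDir, "extractor.rds"))
    h <- trainingHistory(model)
    say("train: final loss %.4f, train acc %.3f, val acc %.3f",
        tail(h$loss, 1), tail(h$trainAcc, 1), tail(h$valAcc, 1))
    model
  })

  feats <- stage("extract", {
    f <- extractFeatures(ex, ws, tap = cfg$cnn$tap)
    writeFeatureCSV(f, file.path(outDir, "features_cnn.csv"))
    f
  })

  sel <- stage("select", {
    cvRows <- windowSplit(feats) %in% c("train", "test")
    wv <- relieffWeights(featureValues(feats)[cvRows, , drop = FALSE],
                         windowLabels(feats)[cvRows],
                         k = cfg$relieff$k, threshold = cfg$relieff$threshold)
    writeWeightsCSV(wv, file.path(outDir, "relieff_weights.csv"))
    fSel <- selectFeatures(feats, wv)
    writeFeatureCSV(fSel, file.path(outDir, "features_selected.csv"))
    coords <- topFeatureCoords(feats, wv)
    data.table::fwrite(coords, file.path(outDir, "feature_coords_3d.csv"))
    say("select: %d of %d features kept", length(keptFeatures(wv)),
        length(featureWeights(wv)))
    list(features = fSel, weights = wv)
  })

  reports <- stage("classify", {
    cvRows <- which(windowSplit(sel$features) %in% c("train", "test"))
    Xcv <- featureValues(sel$features)[cvRows, , drop = FALSE]
    yCV <- droplevels(windowLabels(sel$features)[cvRows])
    foldid <- .makeFolds(yCV, cfg$classify$folds, cfg$seed + 4L)
    reps <- list()
    for (kind in cfg$classify$classifiers) {
      r <- crossValidate(Xcv, yCV, kind = kind, folds = cfg$classify$folds,
                         seed = cfg$seed + 4L, foldid = foldid,
                         condition = "IEDL")
      writeReport(r, file.path(outDir, sprintf("report_%s.json", kind)))
      write.csv(r@confusion,
                file.path(outDir, sprintf("confusion_%s.csv", kind)))
      say("classify %s: mean accuracy %.4f", kind, meanAccuracy(r))
      reps[[kind]] <- r
    }
    summaryDf <- comparisonTable(reps)
    data.table::fwrite(summaryDf, file.path(outDir, "summary.csv"))
    reps
  })

  perSubject <- stage("per-subject", {
    if (cfg$data$subjects >= 2L) {
      tbl <- perSubjectEval(ws, extractor = ex,
                            classifiers = cfg$classify$classifiers,
                            folds = cfg$classify$folds, seed = cfg$seed + 4L,
                            relieffK = cfg$relieff$k,
                            relieffThreshold = cfg$relieff$threshold)
      data.table::fwrite(tbl, file.path(outDir, "per_subject.csv"))
      tbl
    } else NULL
  })

  manifest <- stage("manifest", {
    files <- setdiff(list.files(outDir, recursive = TRUE),
                     "manifest.csv")
    mf <- data.frame(file = files,
                     md5 = unname(tools::md5sum(file.path(outDir, files))))
    data.table::fwrite(mf, file.path(outDir, "manifest.csv"))
    file.path(outDir, "manifest.csv")
  })

  invisible(list(config = cfg, windows = ws, extractor = ex,
                 manual = manual, features = sel$features,
                 weights = sel$weights, reports = reports,
                 perSubject = perSubject, manifest = manifest))
}
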