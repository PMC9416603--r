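# Classifier benchmarking under stratified five-fold cross-validation, and
# the condition-comparison grid (single-stream / dual-stream / manual
# features, single- and fused-modality).

.CLASSIFIERS <- c("SVM", "KNN", "DT", "RF")

# Stratified fold assignment; deterministic given seed.
.makeFolds <- function(y, folds, seed) {
  y <- droplevels(as.factor(y))
  tab <- table(y)
  if (any(tab < folds))
    stop("stratification violated: class '",
         names(tab)[which.min(tab)], "' has ", min(tab), " < ", folds,
         " members")
  foldid <- integer(length(y))
  .withSeed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  foldid
}

.fitPredict <- function(kind, xtr, ytr, xte, seed) {
  ytr <- factor(ytr)
  switch(kind,
    SVM = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1, scale = FALSE)
      predict(fit, xte)
    },
    KNN = class::knn(xtr, xte, ytr, k = 5),
    DT = {
      df <- data.frame(.y = ytr, xtr, check.names = FALSE)
      # fully grown Gini tree (no cost-complexity pruning)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(minsplit = 2,
                                                         minbucket = 1,
                                                         cp = 0))
      predict(fit, data.frame(xte, check.names = FALSE), type = "class")
    },
    RF = .withSeed(seed, {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 100)
      predict(fit, xte)
    }),
    stop("unknown classifier '", kind, "' (use SVM, KNN, DT or RF)"))
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Out-of-fold evaluation with per-fold z-scoring fitted on the training
#' folds only (no leakage).  Folds are stratified by class and deterministic
#' given the seed; a precomputed \code{foldid} can be supplied so several
#' feature sets are compared on identical folds.
#'
#' @param X Windows x features matrix or \linkS4class{MotionFeatures}.
#' @param y Labels (taken from X when it is a MotionFeatures).
#' @param kind "SVM" (radial kernel, C = 1), "KNN" (k = 5), "DT" (CART) or
#'   "RF" (100 trees).
#' @param folds Number of folds (5).
#' @param seed Seed for fold assignment and classifier fitting.
#' @param standardize Per-fold z-scoring (default TRUE).
#' @param foldid Optional precomputed fold assignment.
#' @param condition Condition label recorded in the report.
#' @return An \linkS4class{EvaluationReport}.
#' @export
crossValidate <- function(X, y = NULL, kind = "SVM", folds = 5L, seed = 1L,
                          standardize = TRUE, foldid = NULL,
                          condition = "features") {
  if (is(X, "MotionFeatures")) {
    y <- windowLabels(X)
    X <- featureValues(X)
  }
  stopifnot(is.matrix(X))
  y <- droplevels(as.factor(y))
  if (nrow(X) < folds * nlevels(y))
    stop("need at least folds x classes rows")
  if (is.null(foldid)) foldid <- .makeFolds(y, folds, seed)
  acc <- numeric(folds)
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(truth = levels(y), pred = levels(y)))
  for (f in seq_len(folds)) {
    tr <- foldid != f; te <- !tr
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stop("class absent from training folds")
    xtr <- X[tr, , drop = FALSE]; xte <- X[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, sd); sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
    }
    pred <- .fitPredict(kind, xtr, y[tr], xte, seed + 1000L * f)
    pred <- factor(as.character(pred), levels = levels(y))
    acc[f] <- mean(pred == y[te])
    conf <- conf + unclass(table(y[te], pred))
  }
  new("EvaluationReport", condition = condition, classifier = kind,
      foldAccuracy = acc, confusion = conf, seed = as.integer(seed))
}

.CNN_CONDITIONS <- c("ISL", "ESL", "IESL", "IEDL")

# Features for one comparison condition; trains a CNN when needed.  With
# tap = NULL the published protocol applies: single-stream conditions use
# the FC tap (network minus output layer), while IEDL reserves the features
# before the fully-connected layer (fusion320) and ReliefF-filters them.
.conditionFeatures <- function(ws, condition, epochs, batchSize, lr, seed,
                               relieffK, relieffThreshold, tap, verbose) {
  if (condition %in% .CNN_CONDITIONS) {
    ex <- switch(condition,
                 ISL = buildSingleStream("imu", seed = seed),
                 ESL = buildSingleStream("emg", seed = seed),
                 IESL = buildSingleStream("fused", seed = seed),
                 IEDL = buildDualStream(seed = seed))
    ex <- trainExtractor(ex, ws, epochs = epochs, batchSize = batchSize,
                         lr = lr, seed = seed, verbose = verbose)
    if (is.null(tap))
      tap <- if (condition == "IEDL") "fusion320" else "fc32"
    feats <- extractFeatures(ex, ws, tap = tap)
    if (condition == "IEDL") {
      cvRows <- windowSplit(feats) %in% c("train", "test")
      wv <- relieffWeights(featureValues(feats)[cvRows, , drop = FALSE],
                           windowLabels(feats)[cvRows],
                           k = relieffK, threshold = relieffThreshold)
      feats <- selectFeatures(feats, wv)
    }
    feats
  } else {
    manualCondition(ws, condition)
  }
}

# Column subset of a full manual feature bank for a condition code (so the
# comparison grid computes the bank once).
.manualSubsetCols <- function(featureNames, condition) {
  parts <- strsplit(condition, "+", fixed = TRUE)[[1]]
  keep <- character()
  for (p in parts) {
    s <- .manualConditionSets(p)
    for (f in s$emg)
      keep <- c(keep, paste("emg", .MUSCLES, f, sep = "_"))
    for (f in s$imu)
      keep <- c(keep, paste("imu", .IMU_CHANNELS, f, sep = "_"))
  }
  which(featureNames %in% keep)
}

#' Run the condition-comparison grid
#'
#' Evaluates feature-extraction conditions side by side on identical
#' cross-validation folds: "ISL"/"ESL"/"IESL" are single-stream CNN features
#' from IMU, EMG and channel-stacked fused input; "IEDL" is the dual-stream
#' CNN with ReliefF selection at the 0.1 threshold; manual codes
#' (e.g. "ETF", "ITD", "ETF+ITF") select classical feature subsets.
#' CNN extractors are fitted on the training split; cross-validation runs
#' over the union of the training and test windows (the published protocol,
#' which is mildly optimistic for the CNN conditions since the extractor has
#' seen the training windows — see the package vignette).
#'
#' @param ws A \linkS4class{WindowSet} with split assigned.
#' @param conditions Character vector of condition codes.
#' @param classifiers Subset of SVM/KNN/DT/RF.
#' @param epochs,batchSize,lr CNN training settings.
#' @param folds,seed Cross-validation settings (same folds across
#'   conditions).
#' @param relieffK,relieffThreshold ReliefF settings for IEDL.
#' @param tap CNN feature tap ("fc32" or "fusion320") forced for every CNN
#'   condition; the default NULL applies the published protocol — fc32 for
#'   the single-stream conditions, fusion320 (then ReliefF) for IEDL.
#' @param verbose Print progress.
#' @return List of \linkS4class{EvaluationReport}, one per
#'   (condition, classifier); see [comparisonTable()].
#' @export
runComparison <- function(ws, conditions = c("ISL", "ESL", "IESL", "IEDL"),
                          classifiers = .CLASSIFIERS, epochs = 30L,
                          batchSize = 64L, lr = 1e-3, folds = 5L, seed = 1L,
                          relieffK = 10L, relieffThreshold = 0.1,
                          tap = NULL, verbose = FALSE) {
  stopifnot(is(ws, "WindowSet"))
  bad <- setdiff(classifiers, .CLASSIFIERS)
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "))
  cvRows <- which(ws@split %in% c("train", "test"))
  yCV <- droplevels(ws@label[cvRows])
  foldid <- .makeFolds(yCV, folds, seed)
  manualFull <- if (any(!conditions %in% .CNN_CONDITIONS))
    extractManualFeatures(ws)
  reports <- list()
  for (cond in conditions) {
    if (verbose) message("condition ", cond)
    Xall <- if (cond %in% .CNN_CONDITIONS) {
      feats <- .conditionFeatures(ws, cond, epochs, batchSize, lr, seed,
                                  relieffK, relieffThreshold, tap, verbose)
      featureValues(feats)
    } else {
      full <- featureValues(manualFull)
      full[, .manualSubsetCols(colnames(full), cond), drop = FALSE]
    }
    for (kind in classifiers) {
      rep_ <- crossValidate(Xall[cvRows, , drop = FALSE], yCV, kind = kind,
                            folds = folds, seed = seed, foldid = foldid,
                            condition = cond)
      reports[[paste(cond, kind, sep = ".")]] <- rep_
    }
  }
  reports
}

#' Summarise comparison reports
#'
#' @param reports List of \linkS4class{EvaluationReport} (from
#'   [runComparison()]).
#' @return data.frame with condition, classifier and mean accuracy.
#' @export
comparisonTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(condition = r@condition, classifier = r@classifier,
               meanAccuracy = meanAccuracy(r), row.names = NULL)))
}

#' Per-subject evaluation table
#'
#' Per-subject five-fold cross-validation of the dual-stream + ReliefF
#' features (fusion320 tap, the published IEDL protocol) under all four
#' classifiers — rows are subjects, columns
#' SVM/KNN/DT/RF plus their average.  By default the extractor is fitted
#' once on the pooled training split and shared across subjects; pass
#' \code{extractor = NULL} to refit per subject.
#'
#' @param ws A \linkS4class{WindowSet} with split and subjects assigned.
#' @param extractor A trained \linkS4class{TrainedExtractor}, or NULL to
#'   train per subject.
#' @param classifiers Subset of SVM/KNN/DT/RF.
#' @param epochs,batchSize,lr Training settings (used when fitting).
#' @param folds,seed CV settings.
#' @param relieffK,relieffThreshold ReliefF settings.
#' @return data.frame: subject, one column per classifier, Average.
#' @export
perSubjectEval <- function(ws, extractor = NULL, classifiers = .CLASSIFIERS,
                           epochs = 30L, batchSize = 64L, lr = 1e-3,
                           folds = 5L, seed = 1L, relieffK = 10L,
                           relieffThreshold = 0.1) {
  stopifnot(is(ws, "WindowSet"))
  subjects <- unique(ws@subject)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  if (is.null(extractor)) {
    sharedEx <- NULL
  } else {
    stopifnot(is(extractor, "TrainedExtractor"), extractor@trained)
    sharedEx <- extractor
  }
  # with a shared extractor the ReliefF selection is part of it: computed
  # once on the pooled train+test windows and applied to every subject
  sharedKeep <- NULL
  if (!is.null(sharedEx)) {
    fAll <- extractFeatures(sharedEx, ws, tap = "fusion320")
    cvAll <- which(windowSplit(fAll) %in% c("train", "test"))
    wvAll <- relieffWeights(featureValues(fAll)[cvAll, , drop = FALSE],
                            droplevels(windowLabels(fAll)[cvAll]),
                            k = relieffK, threshold = relieffThreshold)
    sharedKeep <- keptFeatures(wvAll)
  }
  rows <- list()
  for (sj in subjects) {
    wsS <- ws[ws@subject == sj]
    if (nlevels(droplevels(wsS@label)) < 2L)
      stop("subject ", sj, " has a single class")
    ex <- if (is.null(sharedEx)) {
      trainExtractor(buildDualStream(seed = seed), wsS, epochs = epochs,
                     batchSize = batchSize, lr = lr, seed = seed)
    } else sharedEx
    feats <- extractFeatures(ex, wsS, tap = "fusion320")
    cvRows <- which(windowSplit(feats) %in% c("train", "test"))
    Xcv <- featureValues(feats)[cvRows, , drop = FALSE]
    yCV <- droplevels(windowLabels(feats)[cvRows])
    Xsel <- if (is.null(sharedKeep)) {
      wv <- relieffWeights(Xcv, yCV, k = relieffK,
                           threshold = relieffThreshold)
      selectFeatures(Xcv, wv)
    } else Xcv[, sharedKeep, drop = FALSE]
    foldid <- .makeFolds(yCV, folds, seed)
    accs <- vapply(classifiers, function(kind)
      meanAccuracy(crossValidate(Xsel, yCV, kind = kind, folds = folds,
                                 seed = seed, foldid = foldid,
                                 condition = "IEDL")), numeric(1))
    rows[[sj]] <- data.frame(subject = sj, t(accs),
                             Average = mean(accs), row.names = NULL)
  }
  do.call(rbind, rows)
}

#' 3-D coordinates of the top-weighted features
#'
#' Coordinates for a 3-D scatter of the three highest-ReliefF-weight
#' features, the usual visual check of class separation.
#'
#' @param X Windows x features matrix or \linkS4class{MotionFeatures}.
#' @param wv A \linkS4class{ReliefFWeights} on the same columns.
#' @param y Labels (taken from X when possible).
#' @return data.frame(window, x, y, z, label).
#' @export
topFeatureCoords <- function(X, wv, y = NULL) {
  if (is(X, "MotionFeatures")) {
    y <- windowLabels(X)
    X <- featureValues(X)
  }
  stopifnot(is(wv, "ReliefFWeights"), ncol(X) == length(wv@weights))
  top <- order(wv@weights, decreasing = TRUE)[1:3]
  data.frame(window = seq_len(nrow(X)), x = X[, top[1]], y = X[, top[2]],
             z = X[, top[3]], label = as.character(y))
}

#' Serialise / restore an evaluation report
#'
#' Lossless JSON round-trip of an \linkS4class{EvaluationReport}.
#'
#' @param report An \linkS4class{EvaluationReport}.
#' @param path JSON file path.
#' @return \code{writeReport} returns \code{path} invisibly;
#'   \code{readReport} the report.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  jsonlite::write_json(list(
    condition = report@condition, classifier = report@classifier,
    foldAccuracy = report@foldAccuracy,
    confusion = unclass(report@confusion),
    classes = rownames(report@confusion), seed = report@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- matrix(as.integer(x$confusion), length(x$classes),
                 dimnames = list(truth = x$classes, pred = x$classes))
  new("EvaluationReport", condition = x$condition, classifier = x$classifier,
      foldAccuracy = as.numeric(x$foldAccuracy), confusion = conf,
      seed = as.integer(x$seed))
}
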