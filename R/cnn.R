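# The dual-stream convolutional feature extractor: two parallel branches
# (EMG 4x600, IMU 3x600), each conv(1x101, depth 16) -> maxpool(1x10) ->
# conv(3x11 or 2x11, depth 8) -> maxpool(2x2), flattened to 1x160, fused by
# concatenation to 1x320, mapped by a fully-connected layer to 1x32, and
# closed by a softmax output layer.  After training, the network minus its
# output layer is the feature extractor.

#' Convolutional branch specification
#'
#' The printed branch geometry: first convolution 1 x 101 with depth 16,
#' pool 1 x 10, second convolution 3 x 11 (EMG, 4 channels) or 2 x 11
#' (IMU, 3 channels) with depth 8, pool 2 x 2; valid stride-1 convolutions
#' and non-overlapping pooling.  "fused" stacks both modalities to 7 x 600
#' and uses the 3 x 11 second kernel.
#'
#' @param modality "emg", "imu" or "fused".
#' @return List describing the branch (editable before [outputShape()]).
#' @export
branchSpec <- function(modality = c("emg", "imu", "fused")) {
  modality <- match.arg(modality)
  ch <- switch(modality, emg = 4L, imu = 3L, fused = 7L)
  kh2 <- switch(modality, emg = 3L, imu = 2L, fused = 3L)
  list(modality = modality, inChannels = ch, inLength = 600L,
       conv1 = c(1L, 101L), depth1 = 16L, pool1 = c(1L, 10L),
       conv2 = c(kh2, 11L), depth2 = 8L, pool2 = c(2L, 2L))
}

#' Dual-stream specification
#'
#' @param nClasses Number of output classes (4 motion modes).
#' @param fcWidth Fully-connected width after fusion (32).
#' @param fcRelu Apply ReLU after the fully-connected layer (default TRUE,
#'   giving non-negative extracted features).
#' @return List with both branch specs, the fusion width (sum of branch
#'   outputs) and head sizes.
#' @export
dualStreamSpec <- function(nClasses = 4L, fcWidth = 32L, fcRelu = TRUE) {
  be <- branchSpec("emg"); bi <- branchSpec("imu")
  fw <- outputShape(be)$flattened + outputShape(bi)$flattened
  list(emg = be, imu = bi, fusionWidth = fw, fcWidth = as.integer(fcWidth),
       nClasses = as.integer(nClasses), fcRelu = fcRelu)
}

#' Feature-map geometry of a branch
#'
#' Propagates the input dimensions through conv1, pool1, conv2 and pool2
#' under valid stride-1 convolution and non-overlapping pooling, and reports
#' the flattened output length.  For the printed architecture this chain is
#' 4x600 -> 4x500x16 -> 4x50x16 -> 2x40x8 -> 1x20x8 = 160 (EMG) and
#' 3x600 -> ... -> 160 (IMU); the fused 7x600 branch flattens to 320.
#'
#' @param spec A branch spec from [branchSpec()] (possibly modified).
#' @return List of c(height, width, depth) per stage plus \code{flattened}.
#' @examples
#' outputShape(branchSpec("emg"))$flattened   # 160
#' @export
outputShape <- function(spec) {
  plan <- .branchPlan(spec)
  s1 <- plan$stage1; s2 <- plan$stage2
  list(conv1 = c(s1$convH, s1$convW, s1$outC),
       pool1 = c(s1$poolH, s1$poolW, s1$outC),
       conv2 = c(s2$convH, s2$convW, s2$outC),
       pool2 = c(s2$poolH, s2$poolW, s2$outC),
       flattened = plan$flattened)
}

.newExtractor <- function(arch, spec, plans, seed, tap = "fc32") {
  params <- .withSeed(seed, {
    p <- lapply(plans, .initBranchParams)
    fusion <- sum(vapply(plans, function(pl) pl$flattened, numeric(1)))
    p$head <- list(Wfc = .initMat(spec$fcWidth, fusion),
                   bfc = numeric(spec$fcWidth),
                   Wout = .initMat(spec$nClasses, spec$fcWidth),
                   bout = numeric(spec$nClasses))
    p
  })
  new("TrainedExtractor", arch = arch, spec = spec, params = params,
      norm = list(), history = data.frame(), tap = tap,
      classLevels = character(), trained = FALSE)
}

#' Build an untrained dual-stream network
#'
#' @param seed Seed for the fan-in-scaled uniform weight initialisation.
#' @param nClasses,fcWidth,fcRelu See [dualStreamSpec()].
#' @return An untrained \linkS4class{TrainedExtractor} with arch "dual".
#' @export
buildDualStream <- function(seed = 1L, nClasses = 4L, fcWidth = 32L,
                            fcRelu = TRUE) {
  spec <- dualStreamSpec(nClasses, fcWidth, fcRelu)
  plans <- list(emg = .branchPlan(spec$emg), imu = .branchPlan(spec$imu))
  .newExtractor("dual", spec, plans, seed)
}

#' Build an untrained single-stream network
#'
#' @param modality "emg", "imu" or "fused" (channel-stacked 7 x 600).
#' @param seed,nClasses,fcWidth,fcRelu As in [buildDualStream()].
#' @return An untrained \linkS4class{TrainedExtractor}.
#' @export
buildSingleStream <- function(modality = c("emg", "imu", "fused"), seed = 1L,
                              nClasses = 4L, fcWidth = 32L, fcRelu = TRUE) {
  modality <- match.arg(modality)
  bs <- branchSpec(modality)
  spec <- list(main = bs, fusionWidth = outputShape(bs)$flattened,
               fcWidth = as.integer(fcWidth), nClasses = as.integer(nClasses),
               fcRelu = fcRelu)
  plans <- list(main = .branchPlan(bs))
  .newExtractor(modality, spec, plans, seed)
}

.extractorPlans <- function(ex) {
  if (ex@arch == "dual")
    list(emg = .branchPlan(ex@spec$emg), imu = .branchPlan(ex@spec$imu))
  else list(main = .branchPlan(ex@spec$main))
}

# (len x n) input matrices per branch for a WindowSet subset.
.modelInputs <- function(ex, ws, sel = seq_len(nWindows(ws))) {
  flat <- function(a) {
    d <- dim(a)
    matrix(aperm(a, c(2, 3, 1)), d[2] * d[3], d[1])
  }
  if (ex@arch == "dual") {
    list(emg = flat(ws@emg[sel, , , drop = FALSE]),
         imu = flat(ws@imu[sel, , , drop = FALSE]))
  } else if (ex@arch == "emg") {
    list(main = flat(ws@emg[sel, , , drop = FALSE]))
  } else if (ex@arch == "imu") {
    list(main = flat(ws@imu[sel, , , drop = FALSE]))
  } else {
    e <- ws@emg[sel, , , drop = FALSE]
    i <- ws@imu[sel, , , drop = FALSE]
    a <- array(0, c(dim(e)[1], 7L, 600L))
    a[, 1:4, ] <- e; a[, 5:7, ] <- i
    list(main = flat(a))
  }
}

# Per-channel z-scoring.  Stats live in ex@norm as list(branch -> list(mean,
# sd)) with one entry per input channel row-block of length 600.
.fitNorm <- function(inputs) {
  lapply(inputs, function(X) {
    nch <- nrow(X) / 600L
    idx <- rep(seq_len(nch), times = 600L)
    mu <- vapply(seq_len(nch), function(c) mean(X[idx == c, ]), numeric(1))
    sg <- vapply(seq_len(nch), function(c) sd(X[idx == c, ]), numeric(1))
    sg[sg == 0] <- 1
    list(mean = mu, sd = sg)
  })
}

.applyNorm <- function(inputs, norm) {
  if (length(norm) == 0L) return(inputs)
  for (nm in names(inputs)) {
    nch <- length(norm[[nm]]$mean)
    idx <- rep(seq_len(nch), times = 600L)
    inputs[[nm]] <- (inputs[[nm]] - norm[[nm]]$mean[idx]) / norm[[nm]]$sd[idx]
  }
  inputs
}

.batchedForward <- function(ex, plans, inputs, chunk = 64L) {
  n <- ncol(inputs[[1]])
  fuse <- NULL; fc <- NULL; prob <- NULL
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    sub <- lapply(inputs, function(X) X[, s:e, drop = FALSE])
    fw <- .modelForward(ex@params, plans, sub, ex@spec$fcRelu)
    fuse <- cbind(fuse, fw$Fin)
    fc <- cbind(fc, fw$Rfc)
    prob <- cbind(prob, fw$prob)
  }
  list(fusion = fuse, fc = fc, prob = prob)
}

#' Forward pass of an extractor
#'
#' Class probabilities for each window pair (softmax over the output layer).
#' Mostly useful for diagnostics; see [extractFeatures()] for the feature
#' tap.
#'
#' @param ex A \linkS4class{TrainedExtractor} (trained or not).
#' @param ws A \linkS4class{WindowSet}.
#' @return n x nClasses matrix of probabilities (rows sum to 1).
#' @export
predictProb <- function(ex, ws) {
  stopifnot(is(ex, "TrainedExtractor"), is(ws, "WindowSet"))
  plans <- .extractorPlans(ex)
  inputs <- .applyNorm(.modelInputs(ex, ws), ex@norm)
  t(.batchedForward(ex, plans, inputs)$prob)
}

#' Train a convolutional extractor
#'
#' Minimises multi-class cross-entropy with Adam (the adaptive-moment
#' gradient method whose canonical learning rate is the printed 0.001) over
#' seeded mini-batches of the training split; the validation split is used
#' for monitoring only.  Inputs are z-scored per channel with statistics
#' fitted on the training split and stored in the extractor.
#'
#' @param ex An untrained \linkS4class{TrainedExtractor} from
#'   [buildDualStream()] / [buildSingleStream()].
#' @param ws A \linkS4class{WindowSet} with split assigned.
#' @param epochs Training epochs (published setting: 200).
#' @param batchSize Mini-batch size (64).
#' @param lr Learning rate (0.001).
#' @param seed Seed for batch shuffling.
#' @param verbose Print per-epoch progress.
#' @return The trained \linkS4class{TrainedExtractor} with history.
#' @export
trainExtractor <- function(ex, ws, epochs = 200L, batchSize = 64L, lr = 1e-3,
                           seed = 1L, verbose = FALSE) {
  stopifnot(is(ex, "TrainedExtractor"), is(ws, "WindowSet"))
  trIdx <- which(ws@split == "train")
  vaIdx <- which(ws@split == "val")
  if (length(trIdx) == 0L) stop("training split is empty")
  yAll <- droplevels(ws@label)
  if (nlevels(droplevels(ws@label[trIdx])) < 2L)
    stop("training split must contain at least 2 classes")
  lev <- levels(yAll)
  if (length(lev) != ex@spec$nClasses)
    stop(sprintf("model has %d output classes but data has %d",
                 ex@spec$nClasses, length(lev)))
  plans <- .extractorPlans(ex)
  inputsTr <- .modelInputs(ex, ws, trIdx)
  ex@norm <- .fitNorm(inputsTr)
  inputsTr <- .applyNorm(inputsTr, ex@norm)
  yTr <- as.integer(factor(ws@label[trIdx], levels = lev))
  haveVal <- length(vaIdx) > 0L
  if (haveVal) {
    inputsVa <- .applyNorm(.modelInputs(ex, ws, vaIdx), ex@norm)
    yVa <- as.integer(factor(ws@label[vaIdx], levels = lev))
  }
  params <- ex@params
  state <- .adamInit(params)
  nTr <- length(trIdx)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     trainAcc = numeric(), valAcc = numeric())
  .withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nTr)
      epLoss <- 0; epCorrect <- 0L
      for (s in seq(1L, nTr, by = batchSize)) {
        e <- min(s + batchSize - 1L, nTr)
        bi <- ord[s:e]
        sub <- lapply(inputsTr, function(X) X[, bi, drop = FALSE])
        yb <- yTr[bi]
        fw <- .modelForward(params, plans, sub, ex@spec$fcRelu,
                            keepCache = TRUE)
        pb <- fw$prob[cbind(yb, seq_along(bi))]
        epLoss <- epLoss - sum(log(pmax(pb, 1e-12)))
        epCorrect <- epCorrect +
          sum(max.col(t(fw$logits), ties.method = "first") == yb)
        grads <- .modelBackward(params, plans, fw, yb, ex@spec$fcRelu)
        upd <- .adamStep(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
      valAcc <- NA_real_
      if (haveVal) {
        exTmp <- ex; exTmp@params <- params
        pv <- .batchedForward(exTmp, plans, inputsVa)$prob
        valAcc <- mean(max.col(t(pv), ties.method = "first") == yVa)
      }
      hist[ep, ] <- list(ep, epLoss / nTr, epCorrect / nTr, valAcc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  train %.3f  val %s", ep,
                        epLoss / nTr, epCorrect / nTr,
                        ifelse(is.na(valAcc), "-", sprintf("%.3f", valAcc))))
    }
  })
  ex@params <- params
  ex@history <- hist
  ex@classLevels <- lev
  ex@trained <- TRUE
  ex
}

#' Extract features with a trained network
#'
#' Runs window pairs through the trained network with the output layer
#' removed.  Tap "fc32" (default) returns the fully-connected layer output
#' (32 features); "fusion320" returns the concatenated branch features
#' before the fully-connected layer (320 for the dual stream, 160/320 for
#' single streams).
#'
#' @param ex A trained \linkS4class{TrainedExtractor}.
#' @param ws A \linkS4class{WindowSet}.
#' @param tap "fc32" or "fusion320".
#' @return A \linkS4class{MotionFeatures} (modality "cnn"), rows in
#'   WindowSet order.
#' @export
extractFeatures <- function(ex, ws, tap = c("fc32", "fusion320")) {
  stopifnot(is(ex, "TrainedExtractor"), is(ws, "WindowSet"))
  tap <- match.arg(tap, choices = c("fc32", "fusion320"),
                   several.ok = FALSE)
  if (!ex@trained)
    warning("extractor has not been trained; features come from the ",
            "initial random weights")
  plans <- .extractorPlans(ex)
  inputs <- .applyNorm(.modelInputs(ex, ws), ex@norm)
  fw <- .batchedForward(ex, plans, inputs)
  vals <- t(if (tap == "fc32") fw$fc else fw$fusion)
  colnames(vals) <- sprintf("cnn_%s_%03d", tap, seq_len(ncol(vals)))
  MotionFeatures(vals, rep("cnn", ncol(vals)), ws@label, ws@split,
                 ws@subject)
}

#' Save / load an extractor checkpoint
#'
#' Self-describing single-file checkpoint (RDS) with spec, weights,
#' normalisation statistics and history.
#'
#' @param ex A \linkS4class{TrainedExtractor}.
#' @param path File path.
#' @return \code{saveExtractor} returns \code{path} invisibly;
#'   \code{loadExtractor} returns the extractor.
#' @export
saveExtractor <- function(ex, path) {
  stopifnot(is(ex, "TrainedExtractor"))
  saveRDS(ex, path)
  invisible(path)
}

#' @rdname saveExtractor
#' @export
loadExtractor <- function(path) {
  ex <- readRDS(path)
  stopifnot(is(ex, "TrainedExtractor"))
  ex
}
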