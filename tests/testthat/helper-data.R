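# Shared fixtures, built once per test run and memoised.  Sizes are chosen
# so the whole suite stays well inside a routine single-CPU run; the
# vignette documents the same scales as the package's reference experiment.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small 2-subject set for unit tests.
smallWindowSet <- function() .memo("smallWS", function() {
  bundles <- generateDataset(defaultSubjectProfiles(2), repsPerMode = 1,
                             duration = 6, seed = 11)
  assignSplit(buildWindowSet(bundles), seed = 12)
})

# Reference experiment: 6 pseudo-subjects x 4 modes x 7 repetitions x 8 s,
# seed 42 (~700 windows per subject).
defaultWindowSet <- function() .memo("defaultWS", function() {
  bundles <- generateDataset(defaultSubjectProfiles(6), repsPerMode = 7,
                             duration = 8, seed = 42)
  assignSplit(buildWindowSet(bundles), seed = 43)
})

# Cohort for the condition-ordering experiment: 6 subjects x 4 modes
# x 2 repetitions x 8 s.
orderingWindowSet <- function(seed) {
  bundles <- generateDataset(defaultSubjectProfiles(6), repsPerMode = 2,
                             duration = 8, seed = seed)
  assignSplit(buildWindowSet(bundles), seed = seed + 1L)
}

# Dual-stream extractor trained 30 epochs on the reference experiment.
defaultDualExtractor <- function() .memo("dualEx42", function() {
  trainExtractor(buildDualStream(seed = 42), defaultWindowSet(),
                 epochs = 30, seed = 42)
})

# IEDL features of the reference experiment: fusion320 tap (features before
# the fully-connected layer) + ReliefF selection at 0.1 over the train+test
# windows (the published protocol).
defaultIEDLFeatures <- function() .memo("iedl42", function() {
  f <- extractFeatures(defaultDualExtractor(), defaultWindowSet(),
                       tap = "fusion320")
  cv <- windowSplit(f) %in% c("train", "test")
  wv <- relieffWeights(featureValues(f)[cv, , drop = FALSE],
                       windowLabels(f)[cv])
  list(features = selectFeatures(f, wv), weights = wv, cvRows = which(cv))
})
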