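# Synthetic gait-signal generator: mode-specific periodic EMG + IMU with
# controlled cycle-to-cycle variability.  EMG = Gaussian activation envelopes
# (per muscle, in cycle phase) x band-limited Gaussian carrier + white noise
# floor; IMU = two-harmonic Fourier series of the jittered cycle phase +
# sensor noise.

.EMG_RATE <- 2000
.IMU_RATE <- 200
.MUSCLES <- c("RF", "TA", "BF", "GA")
.IMU_CHANNELS <- c("acc_y", "gyro_y", "angle_y")

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.env <- function(center, width, amplitude)
  data.frame(center = center, width = width, amplitude = amplitude)

.harm <- function(offset, amp, phase)
  list(offset = offset, amp = amp, phase = phase)

# Fixed per-mode defaults.  Cadences and waveform shapes are free design
# parameters chosen for physiological plausibility: running is fastest and
# largest in amplitude; ramp ascent shares similar heel kinematics with stair
# ascent (IMU ambiguity) and similar muscle activation with level walking
# (EMG ambiguity), so that neither modality alone separates all four modes
# but their fusion does.
.defaultParamTable <- list(
  running = list(
    cadence = 2.6,
    env = list(
      RF = .env(c(0.05, 0.85), c(0.07, 0.06), c(1.8, 0.9)),
      TA = .env(c(0.95, 0.60), c(0.06, 0.08), c(1.5, 0.8)),
      BF = .env(0.80, 0.07, 1.6),
      GA = .env(0.30, 0.08, 2.2)),
    imu = list(
      acc_y   = .harm(1.0, c(0.90, 0.45), c(0.0, 1.1)),
      gyro_y  = .harm(0.0, c(240, 90),    c(0.5, 2.0)),
      angle_y = .harm(5.0, c(42, 12),     c(1.2, 0.3)))),
  level_walk = list(
    cadence = 1.8,
    env = list(
      RF = .env(0.05, 0.08, 0.7),
      TA = .env(c(0.00, 0.65), c(0.06, 0.10), c(0.9, 0.5)),
      BF = .env(0.90, 0.07, 0.6),
      GA = .env(0.45, 0.09, 1.1)),
    imu = list(
      acc_y   = .harm(1.0, c(0.35, 0.15), c(0.3, 1.6)),
      gyro_y  = .harm(0.0, c(130, 45),    c(0.9, 2.4)),
      angle_y = .harm(2.0, c(26, 8),      c(1.5, 0.6)))),
  stair_ascent = list(
    cadence = 1.4,
    env = list(
      RF = .env(0.15, 0.10, 1.4),
      TA = .env(0.55, 0.08, 0.6),
      BF = .env(0.70, 0.08, 0.5),
      GA = .env(0.40, 0.09, 1.3)),
    imu = list(
      acc_y   = .harm(1.12, c(0.22, 0.10), c(0.80, 2.10)),
      gyro_y  = .harm(0.0, c(95, 30),      c(1.20, 2.80)),
      angle_y = .harm(8.0, c(18, 6),       c(1.80, 1.00)))),
  ramp_ascent = list(
    cadence = 1.6,
    env = list(
      RF = .env(0.07, 0.08, 0.95),
      TA = .env(c(0.02, 0.65), c(0.06, 0.10), c(0.85, 0.45)),
      BF = .env(0.86, 0.07, 0.7),
      GA = .env(0.49, 0.09, 1.35)),
    imu = list(
      acc_y   = .harm(1.15, c(0.26, 0.12), c(0.95, 2.30)),
      gyro_y  = .harm(0.0, c(108, 35),     c(1.35, 3.00)),
      angle_y = .harm(9.0, c(20, 6.8),     c(1.95, 1.25))))
)

#' Default generator parameters for a motion mode
#'
#' Returns the fixed, documented parameter set for one of the four motion
#' modes.  The defaults are mutually distinguishable (distinct cadences,
#' envelope phasings and IMU harmonic amplitudes); running has the largest
#' amplitudes and the highest cadence.  The EMG carrier band is 20--500 Hz
#' for every mode.
#'
#' @param mode One of [motionModes()].
#' @return A \linkS4class{GaitParams} object.
#' @examples
#' p <- defaultGaitParams("running")
#' p@cadence
#' @export
defaultGaitParams <- function(mode) {
  .checkMode(mode)
  d <- .defaultParamTable[[mode]]
  new("GaitParams",
      cadence = d$cadence,
      muscleEnvelopes = d$env,
      imuHarmonics = d$imu,
      cycleJitter = 0.03,
      emgNoiseFloor = 0.08,
      imuNoiseSD = c(0.03, 3, 1.0),
      emgBand = c(20, 500))
}

#' Default synthetic subject profiles
#'
#' Deterministic per-subject amplitude and cadence scalings emulating
#' between-subject variability (log-normal, ~8% SD on amplitude, ~5% on
#' cadence).
#'
#' @param n Number of subjects (default 6).
#' @param seed Seed for the profile draw (fixed default so the cohort is
#'   stable).
#' @return List of \linkS4class{SubjectProfile} objects.
#' @export
defaultSubjectProfiles <- function(n = 6L, seed = 202L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    .withSeed(seed + i, {
      amp <- pmin(pmax(exp(rnorm(4, 0, 0.08)), 0.8), 1.25)
      cad <- pmin(pmax(exp(rnorm(1, 0, 0.05)), 0.88), 1.12)
      names(amp) <- .MUSCLES
      new("SubjectProfile", subjectId = sprintf("S%d", i),
          amplitudeScale = amp, cadenceScale = cad, seedOffset = i)
    })
  })
}

#' Apply a subject profile to generator parameters
#'
#' @param params A \linkS4class{GaitParams}.
#' @param profile A \linkS4class{SubjectProfile}.
#' @return Scaled \linkS4class{GaitParams}.
#' @export
scaleGaitParams <- function(params, profile) {
  stopifnot(is(params, "GaitParams"), is(profile, "SubjectProfile"))
  for (m in .MUSCLES)
    params@muscleEnvelopes[[m]]$amplitude <-
      params@muscleEnvelopes[[m]]$amplitude * profile@amplitudeScale[[m]]
  params@cadence <- params@cadence * profile@cadenceScale
  validObject(params)
  params
}

# Continuous cycle phase (in cycles) on the EMG time grid, with per-cycle
# period jitter plus a smooth incommensurate phase wobble whose size scales
# with cycleJitter.  The wobble is what makes cycle-to-cycle similarity
# genuinely degrade with jitter even after per-cycle length normalisation.
.gaitPhase <- function(params, nE, duration) {
  t <- (seq_len(nE) - 1) / .EMG_RATE
  T0 <- 1 / params@cadence
  nc <- ceiling(duration / T0) + 3L
  jit <- pmin(pmax(rnorm(nc, 0, params@cycleJitter), -3 * params@cycleJitter),
              3 * params@cycleJitter)
  periods <- pmax(T0 * (1 + jit), 0.5 * T0)
  bounds <- cumsum(c(0, periods))
  k <- findInterval(t, bounds)          # cycle index >= 1
  phase <- (k - 1) + (t - bounds[k]) / periods[k]
  if (params@cycleJitter > 0) {
    fw <- params@cadence * runif(2, 0.3, 0.8)
    aw <- 0.3 * params@cycleJitter * abs(rnorm(2))
    ps <- runif(2, 0, 2 * pi)
    phase <- phase + aw[1] * sin(2 * pi * fw[1] * t + ps[1]) +
      aw[2] * sin(2 * pi * fw[2] * t + ps[2])
  }
  phase
}

# Periodic Gaussian envelope evaluated at fractional phase f in [0, 1).
.evalEnvelope <- function(env, frac, baseline = 0.05) {
  out <- rep(baseline, length(frac))
  for (b in seq_len(nrow(env))) {
    for (s in c(-1, 0, 1)) {
      z <- (frac - env$center[b] + s) / env$width[b]
      out <- out + env$amplitude[b] * exp(-0.5 * z * z)
    }
  }
  out
}

# Unit-RMS band-limited Gaussian carrier.
.emgCarrier <- function(n, band) {
  bf <- signal::butter(4, band / (.EMG_RATE / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sqrt(mean(x^2))
}

#' Generate one synthetic EMG + IMU recording
#'
#' Simulates a labelled locomotion recording: 4-channel EMG at 2000 Hz and
#' 3-channel IMU at 200 Hz over the same time span.  The same seed and
#' arguments always reproduce the identical bundle; the caller's RNG stream
#' is left untouched.
#'
#' @param params A \linkS4class{GaitParams} (see [defaultGaitParams()]).
#' @param mode One of [motionModes()].
#' @param duration Seconds; must cover at least two gait cycles.
#' @param seed Integer seed.
#' @param meta Optional extra provenance entries.
#' @return A \linkS4class{RecordingBundle}.
#' @examples
#' b <- generateRecording(defaultGaitParams("level_walk"), "level_walk", 4, 1)
#' b
#' @export
generateRecording <- function(params, mode, duration, seed, meta = list()) {
  stopifnot(is(params, "GaitParams"))
  .checkMode(mode)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (duration * params@cadence < 2)
    stop("duration must cover at least two gait cycles (",
         sprintf("%.2f s at cadence %.2f Hz", duration, params@cadence), ")")
  nE <- round(duration * .EMG_RATE)
  nI <- round(duration * .IMU_RATE)
  .withSeed(seed, {
    phase <- .gaitPhase(params, nE, duration)
    frac <- phase - floor(phase)
    emg <- matrix(0, 4, nE, dimnames = list(.MUSCLES, NULL))
    for (m in .MUSCLES) {
      envl <- .evalEnvelope(params@muscleEnvelopes[[m]], frac)
      carrier <- .emgCarrier(nE, params@emgBand)
      emg[m, ] <- envl * carrier +
        if (params@emgNoiseFloor > 0) rnorm(nE, 0, params@emgNoiseFloor) else 0
    }
    idxI <- seq(1L, nE, by = .EMG_RATE / .IMU_RATE)   # shared phase track
    phI <- phase[idxI]
    imu <- matrix(0, 3, nI, dimnames = list(.IMU_CHANNELS, NULL))
    for (ci in seq_along(.IMU_CHANNELS)) {
      h <- params@imuHarmonics[[.IMU_CHANNELS[ci]]]
      x <- h$offset +
        h$amp[1] * cos(2 * pi * phI + h$phase[1]) +
        h$amp[2] * cos(4 * pi * phI + h$phase[2])
      if (params@imuNoiseSD[ci] > 0)
        x <- x + rnorm(nI, 0, params@imuNoiseSD[ci])
      imu[ci, ] <- x
    }
    new("RecordingBundle", emg = emg, imu = imu, mode = mode,
        duration = duration, rateEMG = .EMG_RATE, rateIMU = .IMU_RATE,
        meta = c(list(seed = as.integer(seed), cadence = params@cadence), meta))
  })
}

#' Generate a multi-subject synthetic dataset
#'
#' One recording per (subject, mode, repetition), with per-recording seeds
#' derived deterministically from the dataset seed so bundles are mutually
#' independent yet reproducible.
#'
#' @param profiles List of \linkS4class{SubjectProfile} objects
#'   (see [defaultSubjectProfiles()]).
#' @param modes Character vector of motion modes (default: all four).
#' @param repsPerMode Recordings per (subject, mode).
#' @param duration Seconds per recording.
#' @param seed Integer dataset seed.
#' @return List of \linkS4class{RecordingBundle} objects, length
#'   \code{length(profiles) * length(modes) * repsPerMode}.
#' @export
generateDataset <- function(profiles, modes = motionModes(), repsPerMode = 1L,
                            duration = 8, seed = 42L) {
  if (length(profiles) == 0L) stop("profiles must be non-empty")
  if (length(modes) == 0L) stop("modes must be non-empty")
  for (m in modes) .checkMode(m)
  stopifnot(repsPerMode >= 1L)
  out <- vector("list", length(profiles) * length(modes) * repsPerMode)
  idx <- 0L
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    for (j in seq_along(modes)) {
      params <- scaleGaitParams(defaultGaitParams(modes[j]), prof)
      for (r in seq_len(repsPerMode)) {
        idx <- idx + 1L
        bseed <- (abs(as.integer(seed)) %% 100000L) * 20011L +
          prof@seedOffset * 4093L + j * 257L + r
        out[[idx]] <- generateRecording(
          params, modes[j], duration, bseed,
          meta = list(subject = prof@subjectId, rep = r,
                      sourceId = sprintf("%s_%s_r%d", prof@subjectId,
                                         modes[j], r)))
      }
    }
  }
  out
}
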