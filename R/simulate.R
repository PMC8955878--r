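#' Per-exercise kinematic templates
#'
#' Each of the six exercises is a periodic movement pattern with its own
#' dominant rotation axis, finger-flexion excursion and linear-motion
#' intensity, mirroring the instructed movements: "rolling" is forearm
#' pronation/supination (large roll oscillation), "wrist flexion-extension"
#' a pitch oscillation with moderate finger excursion, "wrist and fingers
#' extension" a slow movement with large flex excursion, "basket" hands-
#' together turning (roll with bent fingers), "hand up-down" elbow bending
#' with strong vertical acceleration, and "hand kneading" slow combined
#' wrist/finger work. Amplitudes are chosen so every pair of exercises is
#' separated by at least one clearly distinct channel.
#'
#' @return data.frame, one row per exercise in canonical label order, with
#'   columns: `roll_amp`, `pitch_amp` (rad), `flex_base`, `flex_exc` (ADC
#'   counts), `acc_amp` (m/s^2), `freq` (Hz), `gz_amp` (rad/s).
#' @export
exercise_kinematics <- function() {
  data.frame(
    exercise = exercise_labels(),
    roll_amp  = c(0.60, 0.10, 0.10, 1.50, 0.25, 0.45),
    pitch_amp = c(0.10, 0.85, 0.35, 0.10, 0.45, 0.65),
    flex_base = c(1850, 1800, 1700, 1820, 1840, 1750),
    flex_exc  = c(60,   500,  950,  40,   350,  700),
    acc_amp   = c(0.30, 0.40, 0.25, 0.50, 1.60, 0.35),
    freq      = c(0.50, 0.55, 0.35, 0.45, 0.60, 0.30),
    gz_amp    = c(0.30, 0.05, 0.05, 0.10, 0.15, 0.20))
}

#' Draw a synthetic subject profile
#'
#' People perform the same instructed exercise with individual amplitude,
#' tempo and hand geometry. A profile carries multiplicative amplitude
#' factors per channel group (attitude, flex, linear acceleration), a
#' movement-tempo factor, a flex-sensor baseline shift (glove fit), random
#' phase offsets and per-exercise idiosyncrasies (subject-by-exercise
#' amplitude interaction). `variation` scales all inter-subject spreads;
#' at the default 1 the spread is large enough that generalization to an
#' unseen subject is measurably harder than pooled cross-validation.
#'
#' @param subject_id character id.
#' @param seed integer seed for the draw.
#' @param variation non-negative spread multiplier, default 1.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, seed, variation = 1) {
  set.seed(seed)
  ln <- function(sdlog) exp(stats::rnorm(1L, 0, sdlog * variation))
  freq_mult <- exp(stats::rnorm(1L, 0, 0.12 * variation))
  # keep tempo within the slow assisted-movement band
  structure(
    list(subject_id = as.character(subject_id),
         amp_att = ln(0.15), amp_flex = ln(0.15), amp_acc = ln(0.20),
         freq_mult = freq_mult,
         flex_shift = stats::rnorm(1L, 0, 120 * variation),
         phase = stats::runif(5L, 0, 2 * pi),
         exercise_amp = stats::setNames(
           exp(stats::rnorm(6L, 0, 0.10 * variation)), exercise_labels()),
         noise_mult = exp(stats::rnorm(1L, 0, 0.10 * variation))),
    class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> %s | att x%.2f flex x%.2f acc x%.2f tempo x%.2f\n",
    x$subject_id, x$amp_att, x$amp_flex, x$amp_acc, x$freq_mult))
  invisible(x)
}

#' Generate one synthetic training session
#'
#' Synthesizes a labelled glove recording: a ground-truth roll/pitch
#' attitude trajectory is generated directly and differentiated for the
#' gyroscope channels; the accelerometer reads gravity rotated into the
#' body frame plus a linear-motion term; flex channels follow the
#' exercise's finger-flexion waveform quantized to integer ADC counts. All
#' channels carry additive Gaussian noise (defaults: 0.2 m/s^2
#' accelerometer, 0.02 rad/s gyro, 8 ADC counts flex). Anomalous variants
#' emulate how patients fail to exercise: `"rest"` leaves the hand static
#' on the table (noise around a fixed attitude and flex baseline),
#' `"low_motion"` scales all movement amplitudes to 10%.
#'
#' The returned session has the true attitude attached as attribute
#' `"truth"` (data.frame of roll/pitch), so orientation-filter accuracy is
#' testable against ground truth.
#'
#' @param profile a [subject_profile()].
#' @param exercise one of [exercise_labels()].
#' @param anomaly_mode `"none"`, `"rest"` or `"low_motion"`.
#' @param duration session length, seconds.
#' @param fs sampling rate, Hz (21 by default).
#' @param seed integer seed; equal seeds give identical sessions.
#' @param noise named list overriding noise standard deviations
#'   (`accel`, `gyro`, `flex`).
#' @return A `glove_session`.
#' @export
generate_session <- function(profile, exercise,
                             anomaly_mode = c("none", "rest", "low_motion"),
                             duration = 60, fs = 21, seed = 1L,
                             noise = list()) {
  stopifnot(inherits(profile, "subject_profile"))
  anomaly_mode <- match.arg(anomaly_mode)
  check_exercise_label(exercise)
  kin <- exercise_kinematics()
  k <- kin[kin$exercise == exercise, ]
  set.seed(seed)
  n <- round(duration * fs)
  sd_acc <- (noise$accel %||% 0.2) * profile$noise_mult
  sd_gyro <- (noise$gyro %||% 0.02) * profile$noise_mult
  sd_flex <- (noise$flex %||% 8) * profile$noise_mult
  g <- 9.81

  time_ms <- floor((seq_len(n) - 1L) * 1000 / fs)
  t <- time_ms / 1000
  motion <- switch(anomaly_mode, none = 1, rest = 0, low_motion = 0.1)
  amp_att <- profile$amp_att * profile$exercise_amp[[exercise]] * motion
  amp_flex <- profile$amp_flex * motion
  amp_acc <- profile$amp_acc * motion
  f <- k$freq * profile$freq_mult
  ph <- profile$phase

  # base attitude: a hand placed on a table sits at a session-specific
  # orientation well away from level, for resting and exercising alike
  roll0 <- stats::rnorm(1L, 0, 0.35)
  pitch0 <- stats::rnorm(1L, 0, 0.35)
  w <- 2 * pi * f
  roll <- roll0 + k$roll_amp * amp_att * sin(w * t + ph[1L])
  pitch <- pitch0 + k$pitch_amp * amp_att * sin(w * t + ph[2L])
  droll <- k$roll_amp * amp_att * w * cos(w * t + ph[1L])
  dpitch <- k$pitch_amp * amp_att * w * cos(w * t + ph[2L])

  acc_motion <- k$acc_amp * amp_acc
  ax <- -g * sin(pitch) + 0.4 * acc_motion * sin(2 * w * t + ph[4L]) +
    stats::rnorm(n, 0, sd_acc)
  ay <- g * sin(roll) * cos(pitch) +
    0.3 * acc_motion * sin(2 * w * t + ph[4L] + 1) +
    stats::rnorm(n, 0, sd_acc)
  az <- g * cos(roll) * cos(pitch) + acc_motion * sin(2 * w * t + ph[5L]) +
    stats::rnorm(n, 0, sd_acc)

  gx <- droll + stats::rnorm(n, 0, sd_gyro)
  gy <- dpitch + stats::rnorm(n, 0, sd_gyro)
  gz <- k$gz_amp * amp_att * sin(w * t + ph[3L]) + stats::rnorm(n, 0, sd_gyro)

  wf <- 2 * pi * f
  base1 <- k$flex_base + profile$flex_shift
  base2 <- 0.9 * k$flex_base + profile$flex_shift
  exc <- k$flex_exc * amp_flex
  f1 <- base1 + exc * 0.5 * (1 + sin(wf * t + ph[3L])) +
    stats::rnorm(n, 0, sd_flex)
  f2 <- base2 + 0.8 * exc * 0.5 * (1 + sin(wf * t + ph[3L] + 0.9)) +
    stats::rnorm(n, 0, sd_flex)
  clamp_adc <- function(x) pmin(pmax(round(x), 0), adc_max())

  s <- glove_session(
    subject_id = profile$subject_id,
    exercise = exercise,
    anomalous = anomaly_mode != "none",
    fs = fs,
    samples = data.frame(
      time_ms = time_ms,
      ax = ax, ay = ay, az = az,
      gx = gx, gy = gy, gz = gz,
      f1 = clamp_adc(f1), f2 = clamp_adc(f2)))
  attr(s, "truth") <- data.frame(roll = roll, pitch = pitch)
  attr(s, "anomaly_mode") <- anomaly_mode
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full multi-subject synthetic dataset
#'
#' Emulates the structure of the evaluation study's recordings: by default
#' 4 subjects, 292 roughly one-minute sessions at 21 Hz of which 96 are
#' anomalous, balanced coverage of the six exercises within every subject,
#' and anomalous sessions split between the rest and low-motion modes.
#' Session durations are drawn uniformly on 65-93 s (mean 79 s).
#'
#' @param n_subjects number of subjects (default 4).
#' @param n_sessions total sessions (default 292).
#' @param n_anomalous anomalous sessions among them (default 96).
#' @param duration_mean mean session length, seconds (default 79; sessions
#'   are drawn uniformly within +/- 14 s of it).
#' @param fs sampling rate, Hz.
#' @param variation inter-subject spread multiplier, see
#'   [subject_profile()].
#' @param seed master seed; everything (profiles, durations, sessions) fans
#'   out from it deterministically.
#' @param dir optional directory; when given, every session is written as a
#'   CSV via [write_session()] plus a `manifest.csv`.
#' @return Object of class `glove_dataset`: list with `sessions` (named
#'   list of `glove_session`) and `manifest` (data.frame with one row per
#'   file: id, subject_id, exercise, anomalous, anomaly_mode, duration,
#'   n_samples, and path when written).
#' @export
generate_dataset <- function(n_subjects = 4L, n_sessions = 292L,
                             n_anomalous = 96L, duration_mean = 79,
                             fs = 21, variation = 1, seed = 1L,
                             dir = NULL) {
  stopifnot(n_subjects >= 1L, n_sessions >= n_subjects,
            n_anomalous <= n_sessions)
  set.seed(seed)
  profile_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  subject_ids <- sprintf("subj%02d", seq_len(n_subjects))
  profiles <- lapply(seq_len(n_subjects), function(i) {
    subject_profile(subject_ids[i], seed = profile_seeds[i],
                    variation = variation)
  })
  # distribute sessions and anomalies evenly across subjects
  cuts <- floor(seq(0, n_sessions, length.out = n_subjects + 1L))
  per_subject <- diff(cuts)
  acuts <- floor(seq(0, n_anomalous, length.out = n_subjects + 1L))
  anom_per_subject <- diff(acuts)

  rows <- list()
  sessions <- list()
  idx <- 0L
  for (si in seq_len(n_subjects)) {
    m <- per_subject[si]
    ex <- rep(exercise_labels(), length.out = m)
    anom <- rep(FALSE, m)
    if (anom_per_subject[si] > 0L) {
      anom[unique(round(seq(1L, m, length.out = anom_per_subject[si])))] <- TRUE
    }
    # top up in case of rounding collisions
    while (sum(anom) < anom_per_subject[si]) anom[which(!anom)[1L]] <- TRUE
    modes <- rep("none", m)
    modes[anom] <- rep(c("rest", "low_motion"), length.out = sum(anom))
    for (j in seq_len(m)) {
      idx <- idx + 1L
      dur <- stats::runif(1L, duration_mean - 14, duration_mean + 14)
      id <- sprintf("%s_s%03d", subject_ids[si], j)
      s <- generate_session(profiles[[si]], ex[j], modes[j],
                            duration = dur, fs = fs,
                            seed = session_seeds[idx])
      sessions[[id]] <- s
      rows[[idx]] <- data.frame(
        id = id, subject_id = subject_ids[si], exercise = ex[j],
        anomalous = anom[j], anomaly_mode = modes[j],
        duration = dur, n_samples = length(s))
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(manifest$id, ".csv"))
    for (i in seq_len(nrow(manifest))) {
      write_session(sessions[[manifest$id[i]]], manifest$path[i])
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(sessions = sessions, manifest = manifest,
                 profiles = profiles),
            class = "glove_dataset")
}

#' @export
print.glove_dataset <- function(x, ...) {
  cat(sprintf(
    "<glove_dataset> %d sessions (%d anomalous) | %d subjects | %.0f s total\n",
    nrow(x$manifest), sum(x$manifest$anomalous),
    length(unique(x$manifest$subject_id)), sum(x$manifest$duration)))
  invisible(x)
}

#' Load a written dataset from its manifest
#'
#' @param dir directory produced by [generate_dataset()] with `dir` set.
#' @return A `glove_dataset` (without profiles).
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf)
  sessions <- lapply(manifest$path, read_session)
  names(sessions) <- manifest$id
  structure(list(sessions = sessions, manifest = manifest),
            class = "glove_dataset")
}
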