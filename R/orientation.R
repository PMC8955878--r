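#' Raw tilt angles from an accelerometer reading
#'
#' Static roll and pitch implied by a single accelerometer vector under the
#' assumption that it measures gravity only:
#' `roll_raw = atan2(ay, az)`, `pitch_raw = atan2(-ax, sqrt(ay^2 + az^2))`.
#' Vectorized over samples. The angles are invariant under uniform rescaling
#' of the vector (atan2 ratio property); the all-zero vector (free fall)
#' leaves the attitude undefined and raises an error.
#'
#' @param ax,ay,az acceleration components, m/s^2.
#' @return List with numeric `roll` and `pitch`, radians.
#' @export
raw_angles <- function(ax, ay, az) {
  if (any(ax == 0 & ay == 0 & az == 0)) {
    stop("undefined attitude: zero acceleration vector", call. = FALSE)
  }
  list(roll = atan2(ay, az),
       pitch = atan2(-ax, sqrt(ay^2 + az^2)))
}

#' Create an orientation filter state
#'
#' State of the discrete complementary filter blending integrated gyroscope
#' rates (high-frequency path) with accelerometer tilt (low-frequency path)
#' through the cutoff constant `A`:
#' `roll[n] = A * (roll[n-1] + gx[n] * dT) + (1 - A) * roll_raw[n]` and the
#' analogous update for pitch driven by `gy`. Yaw is unobservable with an
#' accelerometer/gyro pair (the rotation axis is parallel to gravity) and is
#' never produced.
#'
#' @param A cutoff time constant in `[0, 1]`; larger trusts the gyro more.
#'   Default 0.98.
#' @param roll,pitch initial angles, radians.
#' @param last_time_ms time stamp of the last absorbed sample, or `NA` if no
#'   sample has been absorbed yet (the first sample then initializes the
#'   angles to its raw accelerometer tilt).
#' @return An object of class `orientation_state`.
#' @export
orientation_state <- function(A = 0.98, roll = 0, pitch = 0,
                              last_time_ms = NA_integer_) {
  if (!is.finite(A) || A < 0 || A > 1) {
    stop("A must lie in [0, 1]", call. = FALSE)
  }
  structure(list(A = A, roll = roll, pitch = pitch,
                 last_time_ms = last_time_ms),
            class = "orientation_state")
}

#' @export
print.orientation_state <- function(x, ...) {
  cat(sprintf("<orientation_state> roll %.4f rad, pitch %.4f rad, A = %g\n",
              x$roll, x$pitch, x$A))
  invisible(x)
}

#' Advance the complementary filter by one sample
#'
#' @param state an `orientation_state`.
#' @param sample one-row data.frame (or list) with fields `time_ms, ax, ay,
#'   az, gx, gy`.
#' @return The updated `orientation_state`.
#' @export
complementary_update <- function(state, sample) {
  stopifnot(inherits(state, "orientation_state"))
  if (is.na(state$last_time_ms)) {
    # first sample: no gyro term, angles snap to the raw accelerometer tilt
    raw <- raw_angles(sample$ax, sample$ay, sample$az)
    state$roll <- raw$roll
    state$pitch <- raw$pitch
    state$last_time_ms <- sample$time_ms
    return(state)
  }
  if (sample$time_ms <= state$last_time_ms) {
    stop("non-increasing time stamp in complementary_update", call. = FALSE)
  }
  dt <- (sample$time_ms - state$last_time_ms) / 1000
  if (sample$ax == 0 && sample$ay == 0 && sample$az == 0) {
    # free fall: raw tilt undefined; hold the previous filtered angles
    warning("zero acceleration vector; holding previous attitude",
            call. = FALSE)
    raw <- list(roll = state$roll, pitch = state$pitch)
  } else {
    raw <- raw_angles(sample$ax, sample$ay, sample$az)
  }
  A <- state$A
  state$roll <- A * (state$roll + sample$gx * dt) + (1 - A) * raw$roll
  state$pitch <- A * (state$pitch + sample$gy * dt) + (1 - A) * raw$pitch
  state$last_time_ms <- sample$time_ms
  state
}

#' Roll/pitch trajectory for a whole session
#'
#' Runs the complementary filter over all samples of a session. The first
#' sample initializes the angles from the raw accelerometer tilt; subsequent
#' samples follow the one-step update. Implemented as a linear recurrence
#' via [stats::filter()] so whole-minute sessions cost one vectorized pass.
#'
#' @param session a `glove_session`, or a data.frame of samples.
#' @param A cutoff time constant, default 0.98.
#' @return data.frame with columns `roll` and `pitch` (radians), one row per
#'   sample.
#' @export
estimate_orientation <- function(session, A = 0.98) {
  df <- if (inherits(session, "glove_session")) session$samples else session
  if (!is.finite(A) || A < 0 || A > 1) stop("A must lie in [0, 1]",
                                            call. = FALSE)
  n <- nrow(df)
  raw <- raw_angles(df$ax, df$ay, df$az)
  if (n == 1L) return(data.frame(roll = raw$roll, pitch = raw$pitch))
  dt <- diff(df$time_ms) / 1000
  if (any(dt <= 0)) {
    stop("time_ms not strictly increasing", call. = FALSE)
  }
  # x[n] = A*(x[n-1] + g[n]*dt[n]) + (1-A)*raw[n]  is the recursion
  # y[n] = A*y[n-1] + u[n] with u[n] = A*g[n]*dt[n] + (1-A)*raw[n]
  recurse <- function(g, raw_angle, init) {
    u <- A * g[-1L] * dt + (1 - A) * raw_angle[-1L]
    out <- stats::filter(u, A, method = "recursive", init = init)
    c(init, as.numeric(out))
  }
  data.frame(
    roll = recurse(df$gx, raw$roll, raw$roll[1L]),
    pitch = recurse(df$gy, raw$pitch, raw$pitch[1L]))
}
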