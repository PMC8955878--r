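#' Create a star-score accumulator
#'
#' Gamified session score: every per-instant binary anomaly classification
#' (1 = correct exercising) is summed into `SCORE(n)`, and the number of
#' stars shown is `floor(numstars / (fs * p * Tmax) * SCORE(n))`, clamped
#' to `[0, numstars]`. The margin-of-error parameter `p = 0.8` means a user
#' classified as correct for 80% of the interaction time already earns the
#' full five stars; the clamp keeps perfect sessions at five.
#' Accumulation starts at the first full window (sample index `ns`).
#'
#' @param fs sampling rate, Hz.
#' @param tmax session length, seconds.
#' @param p margin of error in (0, 1], default 0.8.
#' @param numstars maximum stars, default 5.
#' @param ns window length; classifications exist from this sample on.
#' @return Object of class `score_state`.
#' @export
score_state <- function(fs, tmax, p = 0.8, numstars = 5L, ns = 21L) {
  stopifnot(fs > 0, tmax > 0, p > 0, numstars >= 1L)
  structure(list(score = 0L, n = as.integer(ns) - 1L, ns = as.integer(ns),
                 fs = fs, tmax = tmax, p = p,
                 numstars = as.integer(numstars)),
            class = "score_state")
}

#' @export
print.score_state <- function(x, ...) {
  cat(sprintf("<score_state> SCORE = %d at n = %d -> %d/%d stars\n",
              x$score, x$n, stars_shown(x), x$numstars))
  invisible(x)
}

#' Absorb one binary classification into the score
#'
#' @param state a `score_state`.
#' @param anomaly_class 0 (anomaly) or 1 (correct); fractional scores must
#'   be binarized first (see [binarize_anomaly()]).
#' @return Updated `score_state`.
#' @export
update_score <- function(state, anomaly_class) {
  stopifnot(inherits(state, "score_state"))
  if (length(anomaly_class) != 1L || !anomaly_class %in% c(0, 1)) {
    stop("anomaly_class must be a single 0 or 1; binarize scores first",
         call. = FALSE)
  }
  state$score <- state$score + as.integer(anomaly_class)
  state$n <- state$n + 1L
  state
}

#' Stars currently shown
#'
#' @param state a `score_state`, or a raw SCORE value if `fs`, `tmax` are
#'   given.
#' @param fs,tmax,p,numstars used when `state` is a plain score number.
#' @return Integer star count in `[0, numstars]`.
#' @export
stars_shown <- function(state, fs = NULL, tmax = NULL, p = 0.8,
                        numstars = 5L) {
  if (inherits(state, "score_state")) {
    score <- state$score
    fs <- state$fs; tmax <- state$tmax; p <- state$p
    numstars <- state$numstars
  } else {
    score <- state
    stopifnot(!is.null(fs), !is.null(tmax), fs > 0, tmax > 0, p > 0)
  }
  raw <- floor(numstars / (fs * p * tmax) * score)
  as.integer(max(0, min(numstars, raw)))
}

#' Score a whole classification stream
#'
#' Convenience wrapper folding a stream of binary classifications through
#' [update_score()], returning the stars after each step.
#'
#' @param stream integer vector of 0/1 classifications, one per sample from
#'   the first full window onward.
#' @inheritParams score_state
#' @return List with `score` (final SCORE), `stars` (final star count) and
#'   `stars_trace` (stars after every sample).
#' @export
score_stream <- function(stream, fs, tmax, p = 0.8, numstars = 5L,
                         ns = 21L) {
  if (any(!stream %in% c(0, 1))) {
    stop("stream must be binary; binarize scores first", call. = FALSE)
  }
  cum <- cumsum(stream)
  trace <- vapply(cum, stars_shown, integer(1L), fs = fs, tmax = tmax,
                  p = p, numstars = numstars)
  list(score = if (length(cum)) cum[length(cum)] else 0L,
       stars = if (length(trace)) trace[length(trace)] else 0L,
       stars_trace = trace)
}
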