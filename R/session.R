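#' Construct a session recording
#'
#' A session recording is one labelled training session from the sensor
#' glove: a metadata header (subject, exercise, anomaly flag, sampling rate)
#' plus an ordered table of time-stamped samples. Each sample carries
#' 3-axis acceleration (m/s^2), 3-axis angular velocity (rad/s), two raw
#' flex-sensor ADC counts (0-4095) and the time in integer milliseconds
#' since device start.
#'
#' @param subject_id character scalar identifying the wearer.
#' @param exercise one of [exercise_labels()].
#' @param anomalous logical; `TRUE` if the session records incorrect
#'   (anomalous) exercising.
#' @param fs sampling rate in Hz.
#' @param samples data.frame with columns `time_ms, ax, ay, az, gx, gy, gz,
#'   f1, f2`, ordered by strictly increasing `time_ms`.
#' @return An object of class `glove_session`.
#' @seealso [read_session()], [write_session()], [generate_session()]
#' @export
glove_session <- function(subject_id, exercise, anomalous, fs, samples) {
  s <- structure(
    list(subject_id = as.character(subject_id),
         exercise = exercise,
         anomalous = isTRUE(anomalous),
         fs = as.numeric(fs),
         samples = as.data.frame(samples)),
    class = "glove_session")
  validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks ADC range, strict time monotonicity, finite IMU channels and
#' metadata sanity. Violations raise an error naming the first offending
#' row; nothing is silently repaired.
#'
#' @param session a `glove_session`.
#' @return `session`, invisibly.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "glove_session"))
  check_exercise_label(session$exercise)
  if (!is.finite(session$fs) || session$fs <= 0) {
    stop("sampling rate fs must be a positive number", call. = FALSE)
  }
  df <- session$samples
  missing_cols <- setdiff(sample_columns(), names(df))
  if (length(missing_cols)) {
    stop("samples table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) < 1L) {
    stop("session must contain at least one sample", call. = FALSE)
  }
  imu <- c("ax", "ay", "az", "gx", "gy", "gz")
  for (col in imu) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-finite value in channel %s at row %d", col, bad[1L]),
           call. = FALSE)
    }
  }
  for (col in c("f1", "f2")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > adc_max())
    if (length(bad)) {
      stop(sprintf(
        "flex channel %s out of ADC range [0, %d] at row %d (value %s)",
        col, adc_max(), bad[1L], format(v[bad[1L]])), call. = FALSE)
    }
  }
  dt <- diff(df$time_ms)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop(sprintf("time_ms not strictly increasing at row %d", bad[1L] + 1L),
         call. = FALSE)
  }
  invisible(session)
}

#' @export
print.glove_session <- function(x, ...) {
  cat(sprintf(
    "<glove_session> subject %s | %s | %s | fs = %g Hz | %d samples (%.1f s)\n",
    x$subject_id, x$exercise,
    if (x$anomalous) "anomalous" else "correct",
    x$fs, nrow(x$samples),
    diff(range(x$samples$time_ms)) / 1000))
  invisible(x)
}

#' @export
length.glove_session <- function(x) nrow(x$samples)

#' Write a session recording to CSV
#'
#' One CSV file per session. Metadata travels in `# key: value` comment
#' lines before the column header; floats are serialized with 6 decimal
#' places and time as integer milliseconds, so a write/read roundtrip is
#' lossless at that precision.
#'
#' @param session a valid `glove_session`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  con <- try(file(path, open = "wt"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open path for writing: ", path, call. = FALSE)
  }
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id: %s", session$subject_id),
    sprintf("# exercise: %s", session$exercise),
    sprintf("# anomalous: %s", if (session$anomalous) "true" else "false"),
    sprintf("# fs: %g", session$fs),
    paste(sample_columns(), collapse = ",")), con)
  df <- session$samples[, sample_columns()]
  num <- function(v) sprintf("%.6f", v)
  lines <- paste(
    sprintf("%d", as.integer(round(df$time_ms))),
    num(df$ax), num(df$ay), num(df$az),
    num(df$gx), num(df$gy), num(df$gz),
    sprintf("%d", as.integer(round(df$f1))),
    sprintf("%d", as.integer(round(df$f2))),
    sep = ",")
  writeLines(lines, con)
  invisible(path)
}

#' Read a session recording from CSV
#'
#' Inverse of [write_session()]. The header comments are parsed into
#' metadata; malformed headers raise a format error and any invariant
#' violation (ADC range, non-monotone time) is rejected at read time.
#'
#' @param path path to a session CSV.
#' @return A validated `glove_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 16L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  required <- c("subject_id", "exercise", "anomalous", "fs")
  if (!all(required %in% names(meta))) {
    stop("malformed session header in ", path, ": missing ",
         paste(setdiff(required, names(meta)), collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(df), sample_columns())) {
    stop("malformed session header in ", path,
         ": expected columns ", paste(sample_columns(), collapse = ","),
         call. = FALSE)
  }
  glove_session(
    subject_id = meta$subject_id,
    exercise = meta$exercise,
    anomalous = tolower(meta$anomalous) %in% c("true", "1", "yes"),
    fs = as.numeric(meta$fs),
    samples = df)
}
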