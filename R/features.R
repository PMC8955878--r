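#' Build the smoothed-difference kernel for the flex criterion
#'
#' The flex activity criterion filters the summed flex signal with a short
#' smoothed-difference kernel: a normalized Gaussian window is convolved
#' (full mode) with the difference filter `[-1, 1]`, scaled, and each
#' coefficient rounded half-away-from-zero to one decimal. With the default
#' arguments (size 3, sigma 0.9, scale -2) this yields
#' `c(0.5, 0.4, -0.4, -0.5)`. The kernel annihilates constants (its
#' coefficients sum to zero) and is antisymmetric, so it responds to finger
#' motion while smoothing sensor noise.
#'
#' @param size odd Gaussian window size, >= 3.
#' @param sigma Gaussian standard deviation in samples, > 0.
#' @param scale overall scale factor applied after differencing.
#' @param round_digits decimals for the final rounding, or `NULL` to keep
#'   the exact coefficients.
#' @return Numeric kernel of length `size + 1`, class `smoothing_kernel`.
#' @examples
#' build_kernel()                     # 0.5 0.4 -0.4 -0.5
#' build_kernel(round_digits = NULL)  # exact coefficients
#' @export
build_kernel <- function(size = 3L, sigma = 0.9, scale = -2,
                         round_digits = 1L) {
  if (size %% 2 == 0 || size < 3) {
    stop("kernel size must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0",
                                            call. = FALSE)
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g <- g / sum(g)
  # full convolution with the difference filter [-1, 1]
  d <- c(-g, 0) + c(0, g)
  h <- scale * d
  if (!is.null(round_digits)) {
    # half-away-from-zero, so 0.45 -> 0.5 and -0.45 -> -0.5
    p <- 10^round_digits
    h <- sign(h) * floor(abs(h) * p + 0.5) / p
  }
  structure(h, class = c("smoothing_kernel", "numeric"))
}

#' Acceleration activity criterion
#'
#' Sum of L1 norms of the acceleration vectors over a sample window:
#' `sum(|ax| + |ay| + |az|)`. A hand at rest under constant attitude still
#' produces a gravity floor; motion shows up as variation on top of it.
#'
#' @param window data.frame of samples with columns `ax, ay, az` (a slice of
#'   a session's sample table).
#' @param ns expected window length; defaults to the window's own length.
#' @return Non-negative scalar.
#' @export
s_acc <- function(window, ns = nrow(window)) {
  if (nrow(window) < ns) {
    stop(sprintf("window too short: %d samples < ns = %d", nrow(window), ns),
         call. = FALSE)
  }
  sum(abs(window$ax) + abs(window$ay) + abs(window$az))
}

# valid-mode discrete convolution; embed() row i is (x[i+k-1], ..., x[i]) so
# the matrix product implements the kernel flip of true convolution
conv_valid <- function(x, h) {
  as.numeric(stats::embed(x, length(h)) %*% h)
}

#' Flex activity criterion
#'
#' Sum of absolute values of the summed flex signal `x = f1 + f2` convolved
#' (valid mode: fully overlapping positions only) with the smoothed
#' difference kernel. By distributivity of convolution, filtering `f1 + f2`
#' equals the sum of the individually filtered channels. Constant flexion
#' gives exactly 0 because the kernel sums to zero; replacing the kernel by
#' its reversed negation leaves the result unchanged (absolute values).
#'
#' @param window data.frame of samples with columns `f1, f2`.
#' @param kernel a [build_kernel()] result (default kernel if omitted).
#' @param ns expected window length; defaults to the window's own length.
#' @return Non-negative scalar.
#' @export
s_flex <- function(window, kernel = build_kernel(), ns = nrow(window)) {
  if (nrow(window) < ns) {
    stop(sprintf("window too short: %d samples < ns = %d", nrow(window), ns),
         call. = FALSE)
  }
  if (ns < length(kernel)) {
    stop(sprintf("window length %d below kernel length %d", ns,
                 length(kernel)), call. = FALSE)
  }
  x <- window$f1 + window$f2
  sum(abs(conv_valid(x, as.numeric(kernel))))
}

#' Assemble the 10-element feature vector for one sample
#'
#' Channel order is fixed:
#' `ax, ay, az, f1, f2, gx, gy, gz, roll, pitch`. Flex values stay raw ADC
#' counts; scaling happens only when windows are fed to a model.
#'
#' @param sample one-row data.frame (or list) of sensor fields.
#' @param state an `orientation_state` already updated through this sample.
#' @return Named numeric vector of length 10.
#' @export
make_feature_vector <- function(sample, state) {
  stopifnot(inherits(state, "orientation_state"))
  c(ax = sample$ax, ay = sample$ay, az = sample$az,
    f1 = sample$f1, f2 = sample$f2,
    gx = sample$gx, gy = sample$gy, gz = sample$gz,
    roll = state$roll, pitch = state$pitch)
}

#' Feature matrix for a whole session
#'
#' Runs the complementary filter over the session and binds sensor channels
#' and estimated angles into an `n x 10` matrix, one feature vector per row,
#' channel order as in [make_feature_vector()].
#'
#' @param session a `glove_session`.
#' @param A complementary-filter cutoff constant.
#' @return Numeric matrix with `length(session)` rows and 10 named columns.
#' @export
feature_matrix <- function(session, A = 0.98) {
  df <- session$samples
  ang <- estimate_orientation(session, A = A)
  m <- cbind(ax = df$ax, ay = df$ay, az = df$az,
             f1 = df$f1, f2 = df$f2,
             gx = df$gx, gy = df$gy, gz = df$gz,
             roll = ang$roll, pitch = ang$pitch)
  m
}

#' Assemble a vhistory record stream
#'
#' The record streamed to the user interface per sample: the 10-element
#' feature vector concatenated with the time stamp and the anomaly
#' classification score in `[0, 1]` — 12 values per record.
#'
#' @param features feature matrix (`n x 10`), as from [feature_matrix()].
#' @param time_ms integer sample time stamps, length `n`.
#' @param anomaly_class anomaly scores in `[0, 1]`, length `n` (windows
#'   before the first full one conventionally carry `NA` or 0).
#' @return data.frame with 12 columns: the 10 channels, `time_ms`,
#'   `anomaly_class`.
#' @export
build_vhistory <- function(features, time_ms, anomaly_class) {
  stopifnot(ncol(features) == 10L,
            nrow(features) == length(time_ms),
            length(time_ms) == length(anomaly_class))
  if (any(anomaly_class < 0 | anomaly_class > 1, na.rm = TRUE)) {
    stop("anomaly_class scores must lie in [0, 1]", call. = FALSE)
  }
  out <- as.data.frame(features)
  names(out) <- feature_channels()
  out$time_ms <- as.integer(time_ms)
  out$anomaly_class <- anomaly_class
  out
}

#' @rdname build_vhistory
#' @param vhistory a vhistory data.frame.
#' @param path CSV path.
#' @export
write_vhistory <- function(vhistory, path) {
  expected <- c(feature_channels(), "time_ms", "anomaly_class")
  stopifnot(identical(names(vhistory), expected))
  utils::write.csv(vhistory, path, row.names = FALSE)
  invisible(path)
}

#' @rdname build_vhistory
#' @export
read_vhistory <- function(path) {
  df <- utils::read.csv(path)
  expected <- c(feature_channels(), "time_ms", "anomaly_class")
  if (!identical(names(df), expected)) {
    stop("not a vhistory CSV: ", path, call. = FALSE)
  }
  df
}

#' Fit a per-channel min-max scaler
#'
#' Learns per-channel minima and maxima from training feature vectors only
#' (never test data); applying the scaler maps a training value `x` to
#' `(x - xmin) / (xmax - xmin)`, so scaled training data lies in `[0, 1]`
#' exactly while unseen data may fall outside.
#'
#' @param x matrix of training feature vectors (rows = samples), >= 2 rows.
#' @return Object of class `scaler_params` with fields `xmin`, `xmax`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training vectors", call. = FALSE)
  structure(list(xmin = apply(x, 2L, min), xmax = apply(x, 2L, max)),
            class = "scaler_params")
}

#' Apply a fitted min-max scaler to a window matrix
#'
#' @param m matrix (`ns x channels`) or 3-D window array
#'   (`windows x ns x channels`).
#' @param params a `scaler_params`. A channel whose training range is
#'   degenerate (`xmax == xmin`) maps to 0.
#' @return Scaled object of the same shape.
#' @export
apply_scaler <- function(m, params) {
  stopifnot(inherits(params, "scaler_params"))
  rng <- params$xmax - params$xmin
  k <- length(rng)
  scale_cols <- function(mat) {
    if (ncol(mat) != k) {
      stop(sprintf("channel-count mismatch: matrix has %d, scaler has %d",
                   ncol(mat), k), call. = FALSE)
    }
    out <- sweep(mat, 2L, params$xmin, "-")
    safe <- ifelse(rng == 0, 1, rng)
    out <- sweep(out, 2L, safe, "/")
    out[, rng == 0] <- 0
    out
  }
  if (is.matrix(m)) return(scale_cols(m))
  if (length(dim(m)) == 3L) {
    d <- dim(m)
    flat <- matrix(m, nrow = d[1L] * d[2L], ncol = d[3L])
    out <- scale_cols(flat)
    return(array(out, dim = d, dimnames = dimnames(m)))
  }
  stop("m must be a matrix or a 3-D window array", call. = FALSE)
}

#' @rdname fit_scaler
#' @param params a `scaler_params`.
#' @param path JSON sidecar path.
#' @export
write_scaler <- function(params, path) {
  stopifnot(inherits(params, "scaler_params"))
  jsonlite::write_json(list(xmin = params$xmin, xmax = params$xmax), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname fit_scaler
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(xmin = obj$xmin, xmax = obj$xmax), class = "scaler_params")
}

#' Slice a feature matrix into fixed-length windows
#'
#' @param features feature matrix (`n x channels`).
#' @param ns window length in samples (typically 10, 21 or 42).
#' @param overlapping if `TRUE`, stride-1 windows (`n - ns + 1` of them, as
#'   used for testing); if `FALSE`, consecutive disjoint windows
#'   (`floor(n / ns)`, as used for decision-tree training).
#' @return 3-D array `windows x ns x channels` (0 windows, with a warning,
#'   when the matrix is shorter than `ns`).
#' @export
extract_windows <- function(features, ns, overlapping = TRUE) {
  n <- nrow(features)
  k <- ncol(features)
  if (n < ns) {
    warning(sprintf("feature matrix shorter (%d) than window (%d)", n, ns),
            call. = FALSE)
    return(array(numeric(0), dim = c(0L, ns, k),
                 dimnames = list(NULL, NULL, colnames(features))))
  }
  starts <- if (overlapping) seq_len(n - ns + 1L)
            else seq.int(1L, by = ns, length.out = n %/% ns)
  idx <- outer(starts, 0:(ns - 1L), "+")
  arr <- array(features[as.vector(idx), , drop = FALSE],
               dim = c(length(starts), ns, k))
  dimnames(arr) <- list(NULL, NULL, colnames(features))
  attr(arr, "starts") <- starts
  arr
}
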