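#' Canonical exercise labels
#'
#' The six joint-mobility exercises the glove distinguishes, in the fixed
#' canonical order used everywhere for class indexing: output vectors of the
#' exercise classifier, confusion-matrix axes and metric tables.
#'
#' @return Character vector of length 6.
#' @examples
#' exercise_labels()
#' @export
exercise_labels <- function() {
  c("basket",
    "wrist_flexion_extension",
    "wrist_fingers_extension",
    "rolling",
    "hand_up_down",
    "hand_kneading")
}

#' Validate an exercise label
#'
#' @param x character scalar.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @keywords internal
check_exercise_label <- function(x) {
  if (!is.character(x) || length(x) != 1L || !(x %in% exercise_labels())) {
    stop("unknown exercise label: ", paste(format(x), collapse = ", "),
         "; must be one of: ", paste(exercise_labels(), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# Column order of the sensor sample table; fixed by the feature-vector layout.
sample_columns <- function() {
  c("time_ms", "ax", "ay", "az", "gx", "gy", "gz", "f1", "f2")
}

# Channel order of the 10-element feature vector v.
feature_channels <- function() {
  c("ax", "ay", "az", "f1", "f2", "gx", "gy", "gz", "roll", "pitch")
}

adc_max <- function() 4095L
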