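#' Eye-position trace
#'
#' Container for one test's uniformly sampled eye-position record together
#' with the stimulus it was recorded under and free-form metadata (animal id,
#' group, block time, ground truth when synthetic, ...).
#'
#' @param position Numeric vector of eye position in degrees, uniformly
#'   sampled with no missing values.
#' @param rate Sampling rate in samples/s.
#' @param t0 Time of the first sample in seconds.
#' @param stimulus Optional [stimulus_spec()] describing the test stimulus.
#' @param meta Named list of metadata carried through the pipeline.
#'
#' @return An object of class `"eye_trace"`.
#' @export
eye_trace <- function(position, rate, t0 = 0, stimulus = NULL, meta = list()) {
  if (!is.numeric(position) || length(position) < 2L)
    abort_invalid("'position' must be a numeric vector of length >= 2")
  if (anyNA(position) || any(!is.finite(position)))
    abort_invalid("'position' must contain no missing/non-finite samples")
  check_scalar(rate, "rate", positive = TRUE)
  check_scalar(t0, "t0")
  if (!is.null(stimulus)) stopifnot(inherits(stimulus, "stimulus_spec"))
  structure(list(position = as.numeric(position), rate = rate, t0 = t0,
                 stimulus = stimulus, meta = meta),
            class = "eye_trace")
}

#' Sample times of a trace
#'
#' @param trace An [eye_trace()] or velocity trace.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_time <- function(trace) {
  n <- length(trace$position %||% trace$velocity)
  trace$t0 + (seq_len(n) - 1) / trace$rate
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eye_trace <- function(x, ...) {
  dur <- length(x$position) / x$rate
  cat(sprintf("<eye_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$position), x$rate, dur))
  if (!is.null(x$stimulus))
    cat(sprintf("  stimulus: %s, %g Hz, peak %g deg/s\n",
                x$stimulus$modality, x$stimulus$frequency,
                x$stimulus$peak_velocity))
  keys <- names(x$meta)
  if (length(keys))
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.eye_trace <- function(x, ...) {
  graphics::plot(trace_time(x), x$position, type = "l",
                 xlab = "time (s)", ylab = "eye position (deg)", ...)
  invisible(x)
}
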