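#' Low-pass filter raw eye position
#'
#' Applies a fourth-order low-pass Butterworth filter (15 Hz by default) to
#' the raw eye-position signal.  By default the filter is applied forward and
#' backward (zero phase), so the pass-band amplitude response is the squared
#' one-pass magnitude and no phase lag is introduced; a causal single pass is
#' available for comparison.
#'
#' The filter coefficients are designed with [signal::butter()]; the
#' forward-backward pass itself runs in compiled code with reflective end
#' padding.
#'
#' @param trace An [eye_trace()].
#' @param cutoff Cutoff frequency, Hz (must be below the Nyquist frequency).
#' @param order Filter order.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or causal
#'   single-pass filtering.
#'
#' @return The filtered [eye_trace()]; filter settings are recorded in
#'   `meta$provenance`.
#' @export
lowpass_position <- function(trace, cutoff = 15, order = 4,
                             zero_phase = TRUE) {
  stopifnot(inherits(trace, "eye_trace"))
  check_scalar(cutoff, "cutoff", positive = TRUE)
  check_scalar(order, "order", positive = TRUE)
  if (cutoff >= trace$rate / 2)
    abort_invalid("'cutoff' must be below the Nyquist frequency rate/2")
  n <- length(trace$position)
  if (n <= 3 * (order + 1))
    abort_invalid("trace too short for the requested filter order")
  bf <- signal::butter(order, cutoff / (trace$rate / 2), type = "low")
  npad <- min(n - 1L, as.integer(round(3 * trace$rate / cutoff)))
  if (zero_phase) {
    pos <- .zerophase_iir(trace$position, bf$b, bf$a, npad)
  } else {
    pos <- as.numeric(signal::filter(bf, trace$position))
  }
  out <- trace
  out$position <- pos
  out$meta$provenance <- c(out$meta$provenance,
                           list(lowpass = list(cutoff_hz = cutoff,
                                               order = order,
                                               zero_phase = zero_phase)))
  out
}

# Savitzky-Golay design matrix rows (via signal::sgolay) for derivative
# order 1; row (n+1)/2 is the interior FIR kernel, the outer rows give the
# polynomial-extrapolated endpoint estimates.  Memoized: batch runs reuse
# the same few designs thousands of times.
.sg_cache <- new.env(parent = emptyenv())
sg_design <- function(n, polyorder, rate) {
  key <- paste(n, polyorder, rate, sep = "|")
  got <- .sg_cache[[key]]
  if (is.null(got)) {
    got <- unclass(signal::sgolay(p = polyorder, n = n, m = 1, ts = 1 / rate))
    .sg_cache[[key]] <- got
  }
  got
}

#' Differentiate eye position with a Savitzky-Golay filter
#'
#' Estimates eye velocity as the first derivative of position from a local
#' least-squares polynomial fit over a sliding window (30 ms, order 2 by
#' default).  The window length is rounded to the nearest odd number of
#' samples.  Endpoint samples are handled by evaluating the derivative of the
#' terminal window's polynomial fit at those samples, so the output has the
#' same length and time base as the input.
#'
#' @param trace An [eye_trace()] (typically output of [lowpass_position()]).
#' @param window Window length in seconds (default 0.030).
#' @param polyorder Polynomial order (default 2); the window must span at
#'   least `polyorder + 2` samples.
#'
#' @return An object of class `"velocity_trace"`: list with `velocity`
#'   (deg/s), `rate`, `t0`, `stimulus`, `meta` (including filter provenance).
#' @export
savgol_velocity <- function(trace, window = 0.030, polyorder = 2) {
  stopifnot(inherits(trace, "eye_trace"))
  check_scalar(window, "window", positive = TRUE)
  check_scalar(polyorder, "polyorder", positive = TRUE)
  nw <- round(window * trace$rate)
  if (nw %% 2 == 0) nw <- nw + 1L       # nearest odd, ties round up
  nw <- as.integer(nw)
  if (nw < polyorder + 2)
    abort_invalid("window must span at least polyorder + 2 samples")
  n <- length(trace$position)
  if (n < nw) abort_invalid("trace shorter than the differentiation window")
  fm <- sg_design(nw, polyorder, trace$rate)
  half <- (nw - 1L) %/% 2L
  v <- .fir_center(trace$position, fm[half + 1L, ])
  # endpoint rows: derivative of the polynomial fit over the terminal window
  head_idx <- seq_len(half)
  v[head_idx] <- as.numeric(fm[head_idx, , drop = FALSE] %*%
                              trace$position[seq_len(nw)])
  tail_rows <- (half + 2L):nw
  v[n - nw + tail_rows] <- as.numeric(fm[tail_rows, , drop = FALSE] %*%
                                        trace$position[(n - nw + 1L):n])
  structure(list(velocity = v, rate = trace$rate, t0 = trace$t0,
                 stimulus = trace$stimulus,
                 meta = c(trace$meta,
                          list(savgol = list(window_s = window,
                                             window_samples = nw,
                                             polyorder = polyorder)))),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %d samples @ %g Hz\n",
              length(x$velocity), x$rate))
  invisible(x)
}

#' Full signal conditioning: position to velocity
#'
#' Runs [lowpass_position()] then [savgol_velocity()] — the standard
#' conditioning applied before sinusoid fitting.
#'
#' @inheritParams lowpass_position
#' @inheritParams savgol_velocity
#' @return A `"velocity_trace"`.
#' @export
condition_trace <- function(trace, cutoff = 15, order = 4, window = 0.030,
                            polyorder = 2, zero_phase = TRUE) {
  savgol_velocity(lowpass_position(trace, cutoff, order, zero_phase),
                  window, polyorder)
}
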