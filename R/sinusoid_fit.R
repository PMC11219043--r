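#' Fixed-frequency sinusoid fit to eye velocity
#'
#' Ordinary least squares on the basis \{sin(2*pi*f*t), cos(2*pi*f*t), 1\}
#' over the retained samples.  The frequency is fixed at the stimulus
#' frequency, not fitted.  Amplitude and phase are derived from the two
#' linear coefficients: `amplitude = sqrt(a_sin^2 + a_cos^2)`,
#' `phase = atan2(a_cos, a_sin)`.
#'
#' @param velocity A `"velocity_trace"` (from [condition_trace()]) or a
#'   numeric velocity vector (then `t` or `rate` must be given).
#' @param frequency Fit frequency in Hz; defaults to the trace's stimulus
#'   frequency.
#' @param mask Optional per-sample logical vector, `TRUE` = retained
#'   (default: all samples), or an `"exclusion_mask"`.
#' @param t,rate Sample times (s) or sampling rate, used when `velocity` is
#'   a bare numeric vector.
#'
#' @return An object of class `"sinusoid_fit"` with fields `frequency`,
#'   `amp_sin`, `amp_cos`, `offset`, `amplitude`, `phase`, `residual_rms`
#'   (over the retained samples) and `n_used`.
#' @examples
#' t <- (0:44999) / 1000
#' v <- 3 * sin(2 * pi * t) + 4 * cos(2 * pi * t) + 2
#' fit_sinusoid(v, frequency = 1, t = t)  # amplitude 5, offset 2
#' @export
fit_sinusoid <- function(velocity, frequency = NULL, mask = NULL,
                         t = NULL, rate = NULL) {
  if (inherits(velocity, "velocity_trace")) {
    v <- velocity$velocity
    t <- trace_time(velocity)
    if (is.null(frequency)) frequency <- velocity$stimulus$frequency
  } else {
    v <- as.numeric(velocity)
    if (is.null(t)) {
      if (is.null(rate)) abort_invalid("supply 't' or 'rate' with a bare vector")
      t <- (seq_along(v) - 1) / rate
    }
  }
  if (is.null(frequency)) abort_invalid("'frequency' is required")
  check_scalar(frequency, "frequency", positive = TRUE)
  if (inherits(mask, "exclusion_mask")) mask <- mask$retained
  if (is.null(mask)) mask <- rep(TRUE, length(v))
  if (length(mask) != length(v))
    abort_invalid("mask length must match the velocity trace")
  n_used <- sum(mask)
  if (n_used < 3)
    abort_degenerate("fewer than 3 retained samples")
  tr <- t[mask]
  if (diff(range(tr)) < 1 / frequency)
    abort_degenerate("retained samples span less than one stimulus cycle")
  w <- 2 * pi * frequency
  X <- cbind(sin(w * tr), cos(w * tr), 1)
  xtx <- crossprod(X)
  xty <- crossprod(X, v[mask])
  cf <- tryCatch(drop(solve(xtx, xty)),
                 error = function(e) abort_degenerate(
                   "rank-deficient sinusoid basis on the retained samples"))
  res <- v[mask] - drop(X %*% cf)
  structure(list(frequency = frequency,
                 amp_sin = cf[1], amp_cos = cf[2], offset = cf[3],
                 amplitude = sqrt(cf[1]^2 + cf[2]^2),
                 phase = atan2(cf[2], cf[1]),
                 residual_rms = sqrt(mean(res^2)),
                 n_used = n_used),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_fit> %g Hz: amplitude %.4g deg/s, phase %.3f rad, offset %.3g (rms %.3g, n = %d)\n",
    x$frequency, x$amplitude, x$phase, x$offset, x$residual_rms, x$n_used))
  invisible(x)
}

#' @export
coef.sinusoid_fit <- function(object, ...) {
  c(amp_sin = object$amp_sin, amp_cos = object$amp_cos,
    offset = object$offset, amplitude = object$amplitude,
    phase = object$phase)
}

#' Evaluate a sinusoid fit at given times
#'
#' @param object A `"sinusoid_fit"`.
#' @param t Times in seconds.
#' @param ... Unused.
#' @return Fitted velocity values, deg/s.
#' @export
predict.sinusoid_fit <- function(object, t, ...) {
  w <- 2 * pi * object$frequency
  object$amp_sin * sin(w * t) + object$amp_cos * cos(w * t) + object$offset
}
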