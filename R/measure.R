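#' Measure one VOR/OKR test
#'
#' The central fitting routine.  Raw eye position is conditioned to eye
#' velocity ([condition_trace()]), fit once with a fixed-frequency sinusoid
#' over all samples, desaccaded with [build_exclusion_mask()], and — unless
#' more than `max_excluded` of the samples were excluded, in which case the
#' whole test is rejected — fit a second time on the retained samples.  The
#' amplitude of the second fit is the measure of the eye-movement response;
#' gain is that amplitude divided by the stimulus peak velocity.  Exactly two
#' fit passes are performed.
#'
#' @param trace An [eye_trace()] of one 45 s VOR test or 50 s OKR block.
#' @param frequency Fit frequency, Hz; defaults to the trace's stimulus.
#' @param threshold,pad,min_segment,segment_rule Desaccading parameters, see
#'   [build_exclusion_mask()].
#' @param max_excluded Reject the test when the excluded fraction strictly
#'   exceeds this value (default 0.45).
#' @param cutoff,filter_order,window,polyorder,zero_phase Conditioning
#'   parameters, see [condition_trace()].
#' @param stimulus_peak Stimulus peak velocity used for the gain; defaults to
#'   the trace's stimulus.
#' @param keep_data Keep the velocity trace and mask in the returned object
#'   (set `FALSE` in large batch runs to save memory).
#'
#' @return An object of class `"vor_fit"` with fields `amplitude` (deg/s,
#'   `NA` if invalid), `gain`, `phase`, `offset`, `excluded_fraction`,
#'   `valid`, `reason` (`"ok"`, `"excluded_fraction"` or
#'   `"degenerate_fit"`), the two [fit_sinusoid()] passes (`fit_initial`,
#'   `fit_final`), the exclusion mask, and trace metadata.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`, `as.data.frame`.
#' @examples
#' tr <- synthesize_eye_trace(stimulus_spec(1, 10), true_state(gain = 0.8),
#'                            duration = 45, rate = 1000, seed = 1)
#' fit <- measure_test(tr)
#' coef(fit)["gain"]  # ~ 0.8
#' @export
measure_test <- function(trace, frequency = NULL, threshold = 31,
                         pad = 0.050, min_segment = 0.010,
                         max_excluded = 0.45,
                         segment_rule = c("retained", "excluded"),
                         cutoff = 15, filter_order = 4, window = 0.030,
                         polyorder = 2, zero_phase = TRUE,
                         stimulus_peak = NULL, keep_data = TRUE) {
  stopifnot(inherits(trace, "eye_trace"))
  segment_rule <- match.arg(segment_rule)
  if (is.null(frequency)) {
    if (is.null(trace$stimulus)) abort_invalid("no stimulus on trace; supply 'frequency'")
    frequency <- trace$stimulus$frequency
  }
  if (is.null(stimulus_peak)) {
    if (is.null(trace$stimulus)) abort_invalid("no stimulus on trace; supply 'stimulus_peak'")
    stimulus_peak <- trace$stimulus$peak_velocity
  }
  check_scalar(stimulus_peak, "stimulus_peak", positive = TRUE)
  check_scalar(max_excluded, "max_excluded", nonneg = TRUE)

  vel <- condition_trace(trace, cutoff, filter_order, window, polyorder,
                         zero_phase)
  fit1 <- fit_sinusoid(vel, frequency)
  mask <- build_exclusion_mask(vel, fit1, threshold, pad, min_segment,
                               rule = segment_rule)
  valid <- TRUE
  reason <- "ok"
  fit2 <- NULL
  if (mask$excluded_fraction > max_excluded) {
    valid <- FALSE
    reason <- "excluded_fraction"
  } else {
    fit2 <- tryCatch(fit_sinusoid(vel, frequency, mask = mask),
                     vorlearn_degenerate_fit = function(e) NULL)
    if (is.null(fit2)) {
      valid <- FALSE
      reason <- "degenerate_fit"
    }
  }
  out <- list(
    amplitude = if (valid) fit2$amplitude else NA_real_,
    gain = if (valid) fit2$amplitude / stimulus_peak else NA_real_,
    phase = if (valid) fit2$phase else NA_real_,
    offset = if (valid) fit2$offset else NA_real_,
    excluded_fraction = mask$excluded_fraction,
    valid = valid, reason = reason,
    frequency = frequency, stimulus_peak = stimulus_peak,
    fit_initial = fit1, fit_final = fit2,
    mask = if (keep_data) mask else NULL,
    velocity = if (keep_data) vel else NULL,
    rate = trace$rate, n = length(trace$position),
    duration = length(trace$position) / trace$rate,
    meta = trace$meta,
    params = list(threshold = threshold, pad = pad,
                  min_segment = min_segment, max_excluded = max_excluded,
                  segment_rule = segment_rule, cutoff = cutoff,
                  filter_order = filter_order, window = window,
                  polyorder = polyorder, zero_phase = zero_phase))
  class(out) <- "vor_fit"
  out
}

#' @export
print.vor_fit <- function(x, ...) {
  cat(sprintf("<vor_fit> %g Hz test, %.1f s @ %g Hz sampling\n",
              x$frequency, x$duration, x$rate))
  if (x$valid) {
    cat(sprintf("  amplitude %.4g deg/s  gain %.4g  phase %.3f rad  (%.1f%% excluded)\n",
                x$amplitude, x$gain, x$phase, 100 * x$excluded_fraction))
  } else {
    cat(sprintf("  INVALID (%s), %.1f%% excluded\n", x$reason,
                100 * x$excluded_fraction))
  }
  invisible(x)
}

#' @export
summary.vor_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.vor_fit")
}

#' @export
print.summary.vor_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  pass 1: ")
  print(f$fit_initial)
  if (!is.null(f$fit_final)) {
    cat("  pass 2: ")
    print(f$fit_final)
  }
  if (!is.null(f$mask))
    cat(sprintf("  %d retained segment(s)\n", nrow(f$mask$segments)))
  invisible(x)
}

#' @export
coef.vor_fit <- function(object, ...) {
  c(amplitude = object$amplitude, gain = object$gain,
    phase = object$phase, offset = object$offset)
}

#' @export
predict.vor_fit <- function(object, t = NULL, ...) {
  fit <- object$fit_final %||% object$fit_initial
  if (is.null(t)) t <- (seq_len(object$n) - 1) / object$rate
  predict(fit, t)
}

#' @export
fitted.vor_fit <- function(object, ...) predict(object)

#' @export
residuals.vor_fit <- function(object, ...) {
  if (is.null(object$velocity))
    abort_invalid("fit was run with keep_data = FALSE; residuals unavailable")
  r <- object$velocity$velocity - predict(object)
  attr(r, "retained") <- object$mask$retained
  r
}

#' @export
plot.vor_fit <- function(x, ...) {
  if (is.null(x$velocity))
    abort_invalid("fit was run with keep_data = FALSE; nothing to plot")
  t <- (seq_len(x$n) - 1) / x$rate
  v <- x$velocity$velocity
  graphics::plot(t, v, type = "n", xlab = "time (s)",
                 ylab = "eye velocity (deg/s)", ...)
  ret <- x$mask$retained
  graphics::points(t[!ret], v[!ret], pch = ".", col = "grey60")
  graphics::points(t[ret], v[ret], pch = ".", col = "black")
  graphics::lines(t, predict(x, t), col = "red", lwd = 1.5)
  invisible(x)
}

#' Simulate traces from a fitted test
#'
#' Generates new synthetic eye traces with the fitted amplitude/phase as
#' ground truth and the retained-sample residual RMS as velocity noise —
#' a parametric bootstrap of the measurement.
#'
#' @param object A valid `"vor_fit"`.
#' @param nsim Number of traces.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [eye_trace()] objects.
#' @export
simulate.vor_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$valid) abort_invalid("cannot simulate from an invalid fit")
  spec <- stimulus_spec(object$frequency, object$stimulus_peak)
  st <- true_state(gain = object$gain, phase = object$phase,
                   noise_sd = object$fit_final$residual_rms)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      synthesize_eye_trace(spec, st, duration = object$duration,
                           rate = object$rate))
  })
}

#' @export
as.data.frame.vor_fit <- function(x, ...) {
  m <- x$meta
  data.frame(
    animal = m$animal %||% NA_character_,
    group = m$group %||% NA_character_,
    protocol = m$protocol %||% NA_character_,
    time_min = m$time_min %||% NA_real_,
    test_index = m$test_index %||% NA_integer_,
    frequency = x$frequency,
    peak_velocity = x$stimulus_peak,
    amplitude = x$amplitude,
    gain = x$gain,
    phase = x$phase,
    excluded_fraction = x$excluded_fraction,
    valid = x$valid,
    reason = x$reason,
    true_gain = if (!is.null(m$true)) m$true$gain else NA_real_,
    stringsAsFactors = FALSE)
}
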