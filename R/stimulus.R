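#' Stimulus specification
#'
#' Describes the sinusoidal stimulus used for testing or training: vestibular
#' turntable rotation, optokinetic drum rotation, or a pairing of the two.
#' Amplitudes throughout the package are expressed as peak velocity in deg/s.
#'
#' @param frequency Stimulus frequency in Hz (cycles/s); typically 1 or 0.5.
#' @param peak_velocity Peak stimulus velocity in deg/s; typically 10.
#' @param modality One of `"vestibular"` (turntable alone, in darkness),
#'   `"visual"` (optokinetic drum alone), `"paired_increase"` (turntable
#'   paired with oppositely directed drum motion, driving gain-up learning),
#'   `"paired_decrease"` (drum moving with the head, driving gain-down
#'   learning) or `"none"`.
#'
#' @return An object of class `"stimulus_spec"`.
#' @examples
#' stimulus_spec(frequency = 1, peak_velocity = 10)
#' @export
stimulus_spec <- function(frequency = 1, peak_velocity = 10,
                          modality = c("vestibular", "visual",
                                       "paired_increase", "paired_decrease",
                                       "none")) {
  check_scalar(frequency, "frequency", positive = TRUE)
  check_scalar(peak_velocity, "peak_velocity", positive = TRUE)
  modality <- match.arg(modality)
  structure(list(frequency = frequency, peak_velocity = peak_velocity,
                 modality = modality),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s, %g Hz, peak %g deg/s\n",
              x$modality, x$frequency, x$peak_velocity))
  invisible(x)
}

#' Stimulus velocity waveform
#'
#' Generates the stimulus velocity time series: a pure sinusoid starting at
#' phase zero (sine convention), sampled uniformly.
#'
#' @param spec A [stimulus_spec()].
#' @param duration Duration in seconds (> 0).
#' @param rate Sampling rate in samples/s (>= 100).
#'
#' @return Numeric vector of `round(duration * rate)` velocities in deg/s.
#' @examples
#' v <- make_stimulus_velocity(stimulus_spec(1, 10), duration = 45, rate = 1000)
#' max(v)  # ~ 10 deg/s
#' @export
make_stimulus_velocity <- function(spec, duration, rate = 1000) {
  stopifnot(inherits(spec, "stimulus_spec"))
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(rate, "rate")
  if (rate < 100) abort_invalid("'rate' must be >= 100 samples/s")
  n <- round(duration * rate)
  if (n < 1) abort_invalid("duration * rate rounds to zero samples")
  t <- (seq_len(n) - 1) / rate
  spec$peak_velocity * sin(2 * pi * spec$frequency * t)
}
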