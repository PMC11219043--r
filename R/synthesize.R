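#' Ground-truth response state
#'
#' The true oculomotor response parameters behind one synthetic test, used to
#' validate the measurement pipeline by parameter recovery.
#'
#' @param gain Response gain: eye-velocity amplitude divided by stimulus peak
#'   velocity (dimensionless, >= 0).
#' @param phase Phase in radians relative to the ideal compensatory response
#'   (0 = perfectly compensatory for vestibular tests).
#' @param noise_sd White velocity sensor noise sd, deg/s.
#' @param drift_rate Slow linear position drift, deg/s (a constant velocity
#'   offset absorbed by the fit's intercept term).
#' @param position_noise_sd Independent white noise added to the integrated
#'   position, degrees.
#'
#' @return An object of class `"true_state"`.
#' @export
true_state <- function(gain = 1, phase = 0, noise_sd = 0, drift_rate = 0,
                       position_noise_sd = 0) {
  check_scalar(gain, "gain", nonneg = TRUE)
  check_scalar(phase, "phase")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(drift_rate, "drift_rate")
  check_scalar(position_noise_sd, "position_noise_sd", nonneg = TRUE)
  structure(list(gain = gain, phase = phase, noise_sd = noise_sd,
                 drift_rate = drift_rate,
                 position_noise_sd = position_noise_sd),
            class = "true_state")
}

#' Synthesize a raw eye-position trace
#'
#' Inverse model of the measurement pipeline.  Eye velocity is built as the
#' compensatory response `-gain * stimulus_velocity` shifted by `phase`, plus
#' half-sine saccade velocity pulses, white sensor noise and linear drift;
#' position is the cumulative integral of velocity plus independent position
#' noise.  The ground truth is recorded in the trace metadata.
#'
#' For vestibular tests the compensatory eye movement opposes the head; for
#' visual (OKR) tests the eye follows the stimulus.  Amplitude measurements
#' are phase-agnostic, so this sign convention only matters for phase
#' bookkeeping.
#'
#' @param spec A [stimulus_spec()].
#' @param state A [true_state()].
#' @param saccades A saccade train from [sample_saccade_train()] (or `NULL`);
#'   must be sorted and non-overlapping.
#' @param duration,rate Trace duration (s) and sampling rate (samples/s).
#' @param seed Optional seed for the noise draws.
#'
#' @return An [eye_trace()] whose `meta$true` holds the `true_state` and
#'   `meta$saccades` the event train.
#' @examples
#' tr <- synthesize_eye_trace(stimulus_spec(1, 10), true_state(gain = 0.8),
#'                            duration = 45, rate = 1000, seed = 1)
#' @export
synthesize_eye_trace <- function(spec, state, saccades = NULL,
                                 duration = 45, rate = 1000, seed = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(state, "true_state"))
  validate_saccade_train(saccades)
  n <- round(duration * rate)
  if (n < 2) abort_invalid("duration * rate must give at least 2 samples")
  t <- (seq_len(n) - 1) / rate
  sign_resp <- if (spec$modality == "visual") 1 else -1
  v <- sign_resp * state$gain * spec$peak_velocity *
    sin(2 * pi * spec$frequency * t + state$phase)
  if (!is.null(saccades) && nrow(saccades)) {
    for (i in seq_len(nrow(saccades))) {
      i0 <- floor(saccades$onset[i] * rate) + 1L
      i1 <- min(n, floor((saccades$onset[i] + saccades$duration[i]) * rate))
      if (i1 >= i0) {
        tt <- (t[i0:i1] - saccades$onset[i]) / saccades$duration[i]
        v[i0:i1] <- v[i0:i1] + saccades$peak_velocity[i] * sin(pi * tt)
      }
    }
  }
  with_seed(seed, {
    if (state$noise_sd > 0) v <- v + stats::rnorm(n, 0, state$noise_sd)
    v <- v + state$drift_rate
    pos <- cumsum(v) / rate
    if (state$position_noise_sd > 0)
      pos <- pos + stats::rnorm(n, 0, state$position_noise_sd)
    eye_trace(pos, rate, t0 = 0, stimulus = spec,
              meta = list(true = state, saccades = saccades))
  })
}
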