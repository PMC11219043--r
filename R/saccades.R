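#' Sample a train of saccade-like events
#'
#' Draws saccade/artifact onsets from a homogeneous Poisson process over the
#' trace duration, with peak velocities and durations drawn uniformly from the
#' given ranges and random sign.  Overlapping events are thinned greedily in
#' onset order so the returned train is non-overlapping and sorted.
#'
#' @param duration Trace duration in seconds.
#' @param rate_per_s Mean event rate in events/s (>= 0); 0 returns no events.
#' @param amp_range Range of absolute peak velocities, deg/s.
#' @param dur_range Range of event durations, seconds.
#' @param seed Optional integer seed; identical seeds give identical trains.
#'
#' @return A data frame with columns `onset`, `duration`, `peak_velocity`
#'   (signed deg/s), sorted by onset, with class `"saccade_train"` prepended.
#' @examples
#' sample_saccade_train(45, rate_per_s = 1, seed = 1)
#' @export
sample_saccade_train <- function(duration, rate_per_s,
                                 amp_range = c(100, 300),
                                 dur_range = c(0.020, 0.080),
                                 seed = NULL) {
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(rate_per_s, "rate_per_s", nonneg = TRUE)
  stopifnot(length(amp_range) == 2L, length(dur_range) == 2L,
            all(amp_range > 0), all(dur_range > 0))
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      peak_velocity = numeric(0))
  class(empty) <- c("saccade_train", "data.frame")
  if (rate_per_s == 0) return(empty)
  with_seed(seed, {
    k <- stats::rpois(1L, rate_per_s * duration)
    if (k == 0L) return(empty)
    onset <- sort(stats::runif(k, 0, duration))
    dur <- stats::runif(k, dur_range[1], dur_range[2])
    amp <- stats::runif(k, amp_range[1], amp_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    # greedy thinning: keep an event only if it starts after the previous
    # kept event has ended and ends within the trace
    keep <- logical(k)
    last_end <- -Inf
    for (i in seq_len(k)) {
      if (onset[i] > last_end && onset[i] + dur[i] <= duration) {
        keep[i] <- TRUE
        last_end <- onset[i] + dur[i]
      }
    }
    out <- data.frame(onset = onset[keep], duration = dur[keep],
                      peak_velocity = amp[keep])
    class(out) <- c("saccade_train", "data.frame")
    out
  })
}

# Validates a user-supplied or sampled train: sorted, non-overlapping,
# positive durations.  Returns the train invisibly.
validate_saccade_train <- function(saccades) {
  if (is.null(saccades) || nrow(saccades) == 0L) return(invisible(saccades))
  if (!all(c("onset", "duration", "peak_velocity") %in% names(saccades)))
    abort_invalid("saccade train needs columns onset, duration, peak_velocity")
  if (any(saccades$duration <= 0))
    abort_invalid("saccade durations must be > 0")
  if (is.unsorted(saccades$onset, strictly = FALSE))
    abort_invalid("saccade events must be sorted by onset")
  ends <- saccades$onset + saccades$duration
  if (nrow(saccades) > 1L &&
      any(saccades$onset[-1L] < ends[-nrow(saccades)]))
    abort_invalid("saccade events must not overlap")
  invisible(saccades)
}
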