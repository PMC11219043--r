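#' Experimental session design
#'
#' Encodes the block structure of a behavioral session.  VOR sessions
#' interleave testing blocks (three 45 s tests of the response to the
#' vestibular stimulus alone in darkness, separated by 10 s) with 10 min
#' training blocks repeated three times; pre-training protocols prepend three
#' further training + testing rounds at negative times.  OKR sessions consist
#' of sixty 50 s optokinetic training blocks, each followed by 10 s in
#' darkness, with the response measured on every block.
#'
#' @param protocol One of `"vor_increase"`, `"vor_decrease"`,
#'   `"vestibular_only_pretrain"` (vestibular-only pre-training followed by
#'   VOR-increase training), `"composite"` (VOR-decrease pre-training
#'   followed by VOR-increase training) or `"okr_adaptation"`.
#' @param frequency Test/training stimulus frequency, Hz (1 or 0.5).
#' @param peak_velocity Stimulus peak velocity, deg/s.
#'
#' @return An object of class `"experiment_design"` with fields
#'   `test_times_min` (testing time points in minutes relative to training
#'   onset), `tests_per_block`, `test_duration`, `block_sequence` and the
#'   testing stimulus.
#' @examples
#' experiment_design("vor_increase")
#' @export
experiment_design <- function(protocol = c("vor_increase", "vor_decrease",
                                           "vestibular_only_pretrain",
                                           "composite", "okr_adaptation"),
                              frequency = 1, peak_velocity = 10) {
  protocol <- match.arg(protocol)
  test_stim <- stimulus_spec(frequency, peak_velocity,
                             modality = if (protocol == "okr_adaptation")
                               "visual" else "vestibular")
  train_mod <- switch(protocol,
    vor_increase = "paired_increase",
    vor_decrease = "paired_decrease",
    vestibular_only_pretrain = "paired_increase",
    composite = "paired_increase",
    okr_adaptation = "visual")
  train_stim <- stimulus_spec(frequency, peak_velocity, modality = train_mod)

  if (protocol == "okr_adaptation") {
    blocks <- lapply(seq_len(60L), function(i)
      list(kind = "training", duration = 50, stimulus = train_stim))
    des <- list(protocol = protocol,
                test_times_min = seq_len(60L),
                tests_per_block = 1L, test_duration = 50,
                n_training_blocks = 60L, training_block_s = 50,
                block_sequence = blocks,
                test_stimulus = test_stim, train_stimulus = train_stim)
  } else {
    pre_times <- switch(protocol,
      vestibular_only_pretrain = c(-30, -20, -10),
      composite = c(-30, -20, -10),
      numeric(0))
    pre_mod <- switch(protocol,
      vestibular_only_pretrain = "vestibular",
      composite = "paired_decrease", NA_character_)
    times <- c(pre_times, c(0, 10, 20, 30))
    blocks <- list()
    for (tm in times) {
      blocks[[length(blocks) + 1L]] <-
        list(kind = "testing", duration = 3 * 45 + 2 * 10,
             stimulus = test_stim, time_min = tm)
      if (tm < max(times)) {
        mod <- if (tm < 0) pre_mod else train_mod
        blocks[[length(blocks) + 1L]] <-
          list(kind = "training", duration = 600,
               stimulus = stimulus_spec(frequency, peak_velocity,
                                        modality = mod))
      }
    }
    des <- list(protocol = protocol, test_times_min = times,
                tests_per_block = 3L, test_duration = 45,
                n_training_blocks = length(times) - 1L,
                training_block_s = 600,
                block_sequence = blocks,
                test_stimulus = test_stim, train_stimulus = train_stim)
  }
  structure(des, class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s\n", x$protocol))
  cat(sprintf("  testing time points (min): %s\n",
              paste(x$test_times_min, collapse = ", ")))
  cat(sprintf("  %d test(s) of %g s per testing point; stimulus %g Hz, %g deg/s\n",
              x$tests_per_block, x$test_duration,
              x$test_stimulus$frequency, x$test_stimulus$peak_velocity))
  invisible(x)
}

#' Cohort specification
#'
#' Describes the simulated animal groups: how many animals per group and the
#' group's true gain trajectory across the design's testing time points.
#' Between-animal variability is multiplicative log-normal jitter applied
#' independently at each time point.
#'
#' @param groups Named list, one entry per group (e.g. `WT`, `KO`), each a
#'   list with `n` (animals, >= 1) and `trajectory` (true gains, one per
#'   testing time point of the design).
#' @param jitter_sd sdlog of the log-normal between-animal gain jitter
#'   (default 0.05, i.e. ~5%).
#' @param noise_sd Velocity sensor noise sd, deg/s.
#' @param saccade_rate Saccade/artifact rate, events/s.
#' @param saccade_amp_range,saccade_dur_range Event amplitude (deg/s) and
#'   duration (s) ranges, passed to [sample_saccade_train()].
#' @param phase True response phase, radians.
#' @param drift_rate,position_noise_sd Passed to [true_state()].
#' @param seed Default seed used by [simulate_cohort()].
#'
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups, jitter_sd = 0.05, noise_sd = 2,
                        saccade_rate = 1, saccade_amp_range = c(100, 300),
                        saccade_dur_range = c(0.020, 0.080), phase = 0,
                        drift_rate = 0, position_noise_sd = 0, seed = NULL) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    abort_invalid("'groups' must be a named list")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$n) || gr$n < 1)
      abort_invalid(sprintf("group '%s': n must be >= 1", g))
    if (is.null(gr$trajectory) || !is.numeric(gr$trajectory) ||
        any(gr$trajectory < 0))
      abort_invalid(sprintf("group '%s': trajectory must be non-negative gains", g))
  }
  check_scalar(jitter_sd, "jitter_sd", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(saccade_rate, "saccade_rate", nonneg = TRUE)
  structure(list(groups = groups, jitter_sd = jitter_sd, noise_sd = noise_sd,
                 saccade_rate = saccade_rate,
                 saccade_amp_range = saccade_amp_range,
                 saccade_dur_range = saccade_dur_range, phase = phase,
                 drift_rate = drift_rate,
                 position_noise_sd = position_noise_sd, seed = seed),
            class = "cohort_spec")
}

#' Linear trajectory helper
#'
#' Convenience for programming a linear true-gain ramp across testing points.
#'
#' @param from,to Start and end gains.
#' @param n Number of testing time points.
#' @return Numeric vector of length `n`.
#' @export
ramp_trajectory <- function(from, to, n) {
  check_scalar(from, "from", nonneg = TRUE)
  check_scalar(to, "to", nonneg = TRUE)
  seq(from, to, length.out = n)
}
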