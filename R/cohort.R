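#' Simulate a cohort of behavioral sessions
#'
#' Generates one raw eye-position trace per test per animal following the
#' session design, with each animal's true gain at each testing time point
#' equal to its group trajectory value times independent log-normal jitter.
#' The whole dataset is deterministic under a fixed seed.
#'
#' @param design An [experiment_design()].
#' @param cohort A [cohort_spec()]; every group trajectory must have one gain
#'   per testing time point of the design.
#' @param seed Seed for all randomness (jitter, saccades, noise); defaults to
#'   `cohort$seed`.
#'
#' @return An object of class `"cohort_sim"`: a list with `traces` (list of
#'   [eye_trace()]) and `meta` (data frame with one row per trace: trace_id,
#'   animal, group, time_min, test_index, frequency, peak_velocity,
#'   true_gain), plus the design and cohort spec.
#' @examples
#' des <- experiment_design("vor_increase")
#' coh <- cohort_spec(list(
#'   WT = list(n = 2, trajectory = c(0.8, 0.88, 0.96, 1.04)),
#'   KO = list(n = 2, trajectory = rep(0.8, 4))),
#'   noise_sd = 2, saccade_rate = 1)
#' sim <- simulate_cohort(des, coh, seed = 1)
#' @export
simulate_cohort <- function(design, cohort, seed = cohort$seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(cohort, "cohort_spec"))
  n_times <- length(design$test_times_min)
  for (g in names(cohort$groups)) {
    if (length(cohort$groups[[g]]$trajectory) != n_times)
      abort_invalid(sprintf(
        "group '%s': trajectory has %d values but the design has %d testing time points",
        g, length(cohort$groups[[g]]$trajectory), n_times))
  }
  with_seed(seed, {
    traces <- list()
    rows <- list()
    for (g in names(cohort$groups)) {
      gr <- cohort$groups[[g]]
      for (a in seq_len(gr$n)) {
        animal <- sprintf("%s_%02d", g, a)
        jitter <- exp(stats::rnorm(n_times, 0, cohort$jitter_sd))
        for (ti in seq_len(n_times)) {
          true_gain <- gr$trajectory[ti] * jitter[ti]
          for (k in seq_len(design$tests_per_block)) {
            sacc <- sample_saccade_train(design$test_duration,
                                         cohort$saccade_rate,
                                         cohort$saccade_amp_range,
                                         cohort$saccade_dur_range)
            st <- true_state(gain = true_gain, phase = cohort$phase,
                             noise_sd = cohort$noise_sd,
                             drift_rate = cohort$drift_rate,
                             position_noise_sd = cohort$position_noise_sd)
            tr <- synthesize_eye_trace(design$test_stimulus, st, sacc,
                                       duration = design$test_duration,
                                       rate = 1000)
            id <- sprintf("%s_t%+04d_%d", animal, design$test_times_min[ti], k)
            tr$meta$animal <- animal
            tr$meta$group <- g
            tr$meta$protocol <- design$protocol
            tr$meta$time_min <- design$test_times_min[ti]
            tr$meta$test_index <- k
            tr$meta$trace_id <- id
            traces[[id]] <- tr
            rows[[id]] <- data.frame(
              trace_id = id, animal = animal, group = g,
              time_min = design$test_times_min[ti], test_index = k,
              frequency = design$test_stimulus$frequency,
              peak_velocity = design$test_stimulus$peak_velocity,
              true_gain = true_gain, stringsAsFactors = FALSE)
          }
        }
      }
    }
    meta <- do.call(rbind, rows)
    rownames(meta) <- NULL
    structure(list(traces = traces, meta = meta, design = design,
                   cohort = cohort, seed = seed),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %s: %d traces, %d animals, groups: %s\n",
              x$design$protocol, length(x$traces),
              length(unique(x$meta$animal)),
              paste(names(x$cohort$groups), collapse = ", ")))
  invisible(x)
}
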