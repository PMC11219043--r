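#' Response gain
#'
#' Gain is the ratio of eye-movement amplitude to stimulus amplitude
#' (vestibular for VOR, visual for OKR); both in deg/s peak velocity.
#'
#' @param amplitude Eye-velocity amplitude(s), deg/s.
#' @param stimulus_peak Stimulus peak velocity, deg/s (> 0).
#' @return `amplitude / stimulus_peak`, dimensionless.
#' @examples
#' compute_gain(8, 10)  # 0.8
#' @export
compute_gain <- function(amplitude, stimulus_peak) {
  if (!is.numeric(amplitude)) abort_invalid("'amplitude' must be numeric")
  check_scalar(stimulus_peak, "stimulus_peak")
  if (stimulus_peak <= 0) abort_invalid("'stimulus_peak' must be > 0")
  amplitude / stimulus_peak
}

# Coerce a list of vor_fit objects (or a measurements data frame) to the
# per-test measurements table.
measurements_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "vor_fit")) x <- list(x)
  do.call(rbind, lapply(x, as.data.frame))
}

#' Summarize one testing block
#'
#' Averages the amplitudes of the (typically three) valid tests of one
#' testing block.  Invalid tests are dropped; a block with no valid test has
#' an `NA` mean.
#'
#' @param measurements A list of `"vor_fit"` objects or a measurements data
#'   frame (one row per test) for a single block: all rows must share the
#'   same animal and block time.
#' @return One-row data frame: `animal`, `group`, `time_min`,
#'   `mean_amplitude`, `mean_gain`, `n_valid`.
#' @examples
#' df <- data.frame(animal = "a", group = "WT", time_min = 0,
#'                  amplitude = c(8, 9, 10), gain = c(.8, .9, 1),
#'                  valid = TRUE, peak_velocity = 10)
#' summarize_block(df)  # mean 9, n_valid 3
#' @export
summarize_block <- function(measurements) {
  df <- measurements_table(measurements)
  if (nrow(df) == 0L) abort_invalid("no measurements supplied")
  key <- unique(df[, intersect(c("animal", "time_min"), names(df)),
                   drop = FALSE])
  if (nrow(key) > 1L)
    abort_invalid("measurements from more than one block supplied")
  ok <- df$valid & !is.na(df$amplitude)
  data.frame(
    animal = df$animal[1], group = df$group[1], time_min = df$time_min[1],
    mean_amplitude = if (any(ok)) mean(df$amplitude[ok]) else NA_real_,
    mean_gain = if (any(ok)) mean(df$gain[ok]) else NA_real_,
    n_valid = sum(ok), stringsAsFactors = FALSE)
}

#' Block summaries for a whole measurements table
#'
#' Applies [summarize_block()] to every animal x time-point block.
#'
#' @param measurements Measurements data frame or list of `"vor_fit"`s.
#' @return Data frame of block summaries, ordered by animal then time.
#' @export
summarize_blocks <- function(measurements) {
  df <- measurements_table(measurements)
  parts <- split(df, list(df$animal, df$time_min), drop = TRUE)
  out <- do.call(rbind, lapply(parts, summarize_block))
  out <- out[order(out$animal, out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' VOR learning curve for one animal's session
#'
#' Percent change in VOR amplitude relative to the pre-training baseline:
#' `delta_pct(t) = 100 * (A_t - A_baseline) / A_baseline`, where the
#' baseline is the block at `baseline_time` (time 0, just before training).
#' In pre-training sessions, blocks at negative times are referenced to the
#' session's initial block (the earliest time) instead, so both the
#' pre-training phase and the training phase are expressed relative to their
#' own starting point.  Blocks with no valid test yield no learning point
#' (absent, never imputed).
#'
#' @param blocks Block-summary data frame for one animal (see
#'   [summarize_blocks()]).
#' @param baseline_time Training-phase baseline time in minutes (default 0).
#' @return Data frame of class `"learning_curve"`: `animal`, `group`,
#'   `time_min`, `amplitude`, `delta_pct`, `n_valid`, ordered by time.
#' @examples
#' b <- data.frame(animal = "a", group = "WT", time_min = c(0, 10),
#'                 mean_amplitude = c(5, 6), mean_gain = c(.5, .6),
#'                 n_valid = 3)
#' vor_learning_curve(b)  # +20% at 10 min
#' @export
vor_learning_curve <- function(blocks, baseline_time = 0) {
  stopifnot(is.data.frame(blocks))
  if (length(unique(blocks$animal)) > 1L)
    abort_invalid("one animal at a time; see cohort_learning_curves()")
  blocks <- blocks[order(blocks$time_min), , drop = FALSE]
  ok <- blocks$n_valid >= 1 & !is.na(blocks$mean_amplitude)
  base_row <- which(blocks$time_min == baseline_time & ok)
  if (!length(base_row))
    abort_missing_baseline(sprintf(
      "no valid baseline block at time %g min", baseline_time))
  a0 <- blocks$mean_amplitude[base_row[1]]
  pre <- blocks$time_min < baseline_time
  if (any(pre & ok)) {
    pre_base <- blocks$mean_amplitude[which(pre & ok)[1]]
  } else pre_base <- NA_real_
  keep <- which(ok)
  ref <- ifelse(blocks$time_min[keep] < baseline_time, pre_base, a0)
  out <- data.frame(
    animal = blocks$animal[keep], group = blocks$group[keep],
    time_min = blocks$time_min[keep],
    amplitude = blocks$mean_amplitude[keep],
    delta_pct = 100 * (blocks$mean_amplitude[keep] - ref) / ref,
    n_valid = blocks$n_valid[keep], stringsAsFactors = FALSE)
  out <- out[!is.na(out$delta_pct), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' Learning curves for every animal in a cohort
#'
#' Applies [vor_learning_curve()] per animal; animals with no valid baseline
#' are dropped with a warning.
#'
#' @inheritParams vor_learning_curve
#' @param blocks Block-summary data frame for many animals.
#' @return Combined `"learning_curve"` data frame.
#' @export
cohort_learning_curves <- function(blocks, baseline_time = 0) {
  parts <- split(blocks, blocks$animal)
  out <- list()
  for (a in names(parts)) {
    cur <- tryCatch(vor_learning_curve(parts[[a]], baseline_time),
                    vorlearn_missing_baseline = function(e) NULL)
    if (is.null(cur)) {
      warning(sprintf("animal %s dropped: no valid baseline block", a),
              call. = FALSE)
    } else out[[a]] <- cur
  }
  if (!length(out)) abort_empty_results("no animal had a valid baseline")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("learning_curve", "data.frame")
  res
}

#' OKR adaptation from a 60-block session
#'
#' The pre-training baseline is the mean amplitude of blocks 1-3 and the
#' post-training measure the mean of blocks 58-60 (minutes 58-60); learned
#' change is `100 * (post - baseline) / baseline`.  Intermediate learning is
#' reported at blocks 10, 20, 30, 40 and 50 relative to the same baseline.
#' Invalid blocks (`NA`) are dropped from the triad means; at least one
#' valid block is required in each triad.
#'
#' @param block_amplitudes Numeric vector of 60 per-block amplitudes
#'   (deg/s), `NA` for rejected blocks.
#' @return List of class `"okr_learning"`: `baseline`, `post`, `delta_pct`,
#'   and `curve`, a data frame with `time_min` (10, 20, 30, 40, 50, 60) and
#'   `delta_pct` (the 60 min point uses the post-training triad mean).
#' @examples
#' okr_learning(c(rep(4, 3), rep(NA, 54), rep(5, 3)))$delta_pct  # +25
#' @export
okr_learning <- function(block_amplitudes) {
  if (!is.numeric(block_amplitudes) || length(block_amplitudes) != 60L)
    abort_invalid("'block_amplitudes' must have exactly 60 values")
  triad <- function(idx, label) {
    v <- block_amplitudes[idx]
    if (all(is.na(v)))
      abort_missing_baseline(sprintf("no valid block in the %s triad", label))
    mean(v, na.rm = TRUE)
  }
  baseline <- triad(1:3, "baseline (1-3)")
  post <- triad(58:60, "post-training (58-60)")
  mid <- c(10, 20, 30, 40, 50)
  mid_delta <- 100 * (block_amplitudes[mid] - baseline) / baseline
  curve <- data.frame(
    time_min = c(mid, 60),
    delta_pct = c(mid_delta, 100 * (post - baseline) / baseline))
  curve <- curve[!is.na(curve$delta_pct), , drop = FALSE]
  rownames(curve) <- NULL
  structure(list(baseline = baseline, post = post,
                 delta_pct = 100 * (post - baseline) / baseline,
                 curve = curve),
            class = "okr_learning")
}

#' @export
print.okr_learning <- function(x, ...) {
  cat(sprintf("<okr_learning> baseline %.4g, post %.4g deg/s: dOKR = %+.2f%%\n",
              x$baseline, x$post, x$delta_pct))
  invisible(x)
}

#' Measure every test of a simulated or recorded cohort
#'
#' Runs [measure_test()] on each trace and returns the per-test QC table.
#'
#' @param traces A `"cohort_sim"` (from [simulate_cohort()]) or a list of
#'   [eye_trace()] objects.
#' @param ... Measurement parameters passed to [measure_test()].
#' @return Measurements data frame, one row per test.
#' @export
measure_cohort <- function(traces, ...) {
  if (inherits(traces, "cohort_sim")) traces <- traces$traces
  rows <- lapply(traces, function(tr)
    as.data.frame(measure_test(tr, keep_data = FALSE, ...)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full analysis of a cohort: tests to learning curves
#'
#' Convenience wrapper: [measure_cohort()] then [summarize_blocks()] then
#' [cohort_learning_curves()].
#'
#' @inheritParams measure_cohort
#' @param baseline_time Baseline time in minutes (default 0; for OKR
#'   sessions use [okr_learning()] on the block amplitudes instead).
#' @return List with `measurements`, `blocks` and `curves`.
#' @export
analyze_cohort <- function(traces, baseline_time = 0, ...) {
  meas <- measure_cohort(traces, ...)
  blocks <- summarize_blocks(meas)
  curves <- cohort_learning_curves(blocks, baseline_time)
  list(measurements = meas, blocks = blocks, curves = curves)
}
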