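#' Default pipeline configuration
#'
#' Returns the full configuration list with every analysis parameter at its
#' standard value: 15 Hz fourth-order low-pass, 30 ms order-2
#' Savitzky-Golay differentiation, 31 deg/s residual threshold with 50 ms
#' padding and 10 ms minimum segment, 45% test-rejection rule, and alpha =
#' 0.05.  The simulation section defines a two-group VOR-increase cohort
#' (one group programmed +30% over three 10 min training blocks, one flat).
#'
#' @param seed Seed recorded in the config.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    protocol = "vor_increase",
    design = list(frequency_hz = 1, peak_velocity_degps = 10),
    cohort = list(
      groups = list(
        WT = list(n_animals = 5, trajectory = c(0.8, 0.88, 0.96, 1.04)),
        KO = list(n_animals = 5, trajectory = c(0.8, 0.8, 0.8, 0.8))),
      jitter_sd = 0.05,
      noise_sd_degps = 2,
      saccade_rate_hz = 1,
      saccade_amp_range_degps = c(100, 300),
      saccade_dur_range_ms = c(20, 80)),
    filter = list(cutoff_hz = 15, order = 4, zero_phase = TRUE),
    savgol = list(window_ms = 30, polyorder = 2),
    fit = list(threshold_degps = 31, pad_ms = 50, min_segment_ms = 10,
               max_excluded_fraction = 0.45, segment_rule = "retained"),
    metrics = list(baseline_time_min = 0),
    stats = list(alpha = 0.05))
}

#' Read / write a pipeline configuration
#'
#' YAML round trip; [read_config()] overlays the file on [default_config()]
#' so a partial file is valid and every parameter keeps its default.
#'
#' @param file YAML path.
#' @param config Configuration list (for [write_config()]).
#' @return The configuration list ([read_config()]) or `file` invisibly.
#' @export
read_config <- function(file) {
  if (!file.exists(file)) abort_format(sprintf("no such config: %s", file))
  user <- yaml::read_yaml(file)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) && k != "groups") {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

config_design <- function(config) {
  experiment_design(config$protocol,
                    frequency = config$design$frequency_hz,
                    peak_velocity = config$design$peak_velocity_degps)
}

config_cohort <- function(config) {
  co <- config$cohort
  # the config key is n_animals: a bare "n" is a YAML 1.1 boolean
  cohort_spec(groups = lapply(co$groups, function(g)
                list(n = g$n_animals %||% g$n,
                     trajectory = as.numeric(g$trajectory))),
              jitter_sd = co$jitter_sd,
              noise_sd = co$noise_sd_degps,
              saccade_rate = co$saccade_rate_hz,
              saccade_amp_range = as.numeric(co$saccade_amp_range_degps),
              saccade_dur_range = as.numeric(co$saccade_dur_range_ms) / 1000,
              seed = config$seed)
}

measure_args <- function(config) {
  list(threshold = config$fit$threshold_degps,
       pad = config$fit$pad_ms / 1000,
       min_segment = config$fit$min_segment_ms / 1000,
       max_excluded = config$fit$max_excluded_fraction,
       segment_rule = config$fit$segment_rule,
       cutoff = config$filter$cutoff_hz,
       filter_order = config$filter$order,
       zero_phase = config$filter$zero_phase,
       window = config$savgol$window_ms / 1000,
       polyorder = config$savgol$polyorder)
}

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Simulate a cohort to a directory of trace files
#'
#' Builds the design and cohort from the configuration, simulates, and
#' writes one trace file (+ YAML sidecar) per test.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config_design(config), config_cohort(config),
                         seed = config$seed)
  for (id in names(sim$traces))
    write_trace(sim$traces[[id]], file.path(out_dir, paste0(id, ".tsv")))
  write_tsv(sim$meta, file.path(out_dir, "cohort_meta.tsv"))
  message(sprintf("simulated %d traces to %s", length(sim$traces), out_dir))
  invisible(out_dir)
}

#' Analyze a directory of trace files
#'
#' Reads every trace (sorted by file name for determinism), measures each
#' test, and writes the per-test QC table, block summaries, learning-curve
#' table and a run manifest.
#'
#' @param config Configuration list.
#' @param in_dir Directory of trace files from [run_simulate()] (or
#'   equivalently formatted recordings).
#' @param out_dir Output directory for the result tables.
#' @return List with `measurements`, `blocks`, `curves` (also written as
#'   TSV), invisibly.
#' @export
run_analyze <- function(config, in_dir, out_dir) {
  files <- sort(list.files(in_dir, pattern = "\\.tsv$", full.names = TRUE))
  files <- files[!grepl("cohort_meta\\.tsv$", files)]
  if (!length(files)) abort_empty_results("no trace files found")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traces <- lapply(files, read_trace)
  ma <- measure_args(config)
  message(sprintf("analyzing %d tests (threshold %g deg/s, pad %g ms, max excluded %g%%)",
                  length(traces), ma$threshold, 1000 * ma$pad,
                  100 * ma$max_excluded))
  meas <- do.call(measure_cohort, c(list(traces), ma))
  if (!any(meas$valid))
    abort_empty_results("every test was rejected by the exclusion rule")
  n_inval <- sum(!meas$valid)
  if (n_inval)
    message(sprintf("%d of %d tests rejected", n_inval, nrow(meas)))
  is_okr <- identical(config$protocol, "okr_adaptation")
  blocks <- summarize_blocks(meas)
  if (is_okr) {
    curves <- do.call(rbind, lapply(split(blocks, blocks$animal), function(b) {
      ok <- okr_learning(b$mean_amplitude[order(b$time_min)][1:60])
      data.frame(animal = b$animal[1], group = b$group[1],
                 time_min = ok$curve$time_min, amplitude = NA_real_,
                 delta_pct = ok$curve$delta_pct, n_valid = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
    rownames(curves) <- NULL
  } else {
    curves <- cohort_learning_curves(blocks, config$metrics$baseline_time_min)
  }
  write_tsv(meas, file.path(out_dir, "qc.tsv"))
  write_tsv(blocks, file.path(out_dir, "blocks.tsv"))
  write_tsv(as.data.frame(curves), file.path(out_dir, "learning.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("vorlearn")),
    seed = config$seed,
    n_tests = nrow(meas), n_valid = sum(meas$valid),
    n_rejected = n_inval,
    config = config)
  cfg_tmp <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_tmp)
  manifest$config_md5 <- unname(tools::md5sum(cfg_tmp))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(measurements = meas, blocks = blocks, curves = curves))
}

#' Group statistics on a learning-curve table
#'
#' Runs the standard comparisons on the tidy learning table: Shapiro-Wilk
#' normality per group at the final time point, the group x time
#' repeated-measures ANOVA with Tukey contrasts on the post-training times
#' (the baseline time is excluded: its percent change is identically zero
#' for every animal), and a two-sample t-test between groups at the final
#' time point.
#'
#' @param config Configuration list.
#' @param curves Learning-curve data frame (or path to `learning.tsv`).
#' @param out_file Optional path for the comparisons TSV.
#' @return List with `anova` (an `"rm_anova"`, `NULL` if < 2 groups) and
#'   `comparisons` (data frame, one row per contrast).
#' @export
run_stats <- function(config, curves, out_file = NULL) {
  if (is.character(curves)) curves <- utils::read.table(curves, header = TRUE,
                                                        sep = "\t")
  alpha <- config$stats$alpha
  post <- curves[curves$time_min > config$metrics$baseline_time_min, ,
                 drop = FALSE]
  if (!nrow(post)) abort_empty_results("no post-baseline learning points")
  t_final <- max(post$time_min)
  fin <- post[post$time_min == t_final, , drop = FALSE]
  rows <- list()
  for (g in unique(fin$group)) {
    v <- fin$delta_pct[fin$group == g]
    sw <- tryCatch(shapiro_wilk(v, alpha), vorlearn_error = function(e) NULL)
    if (!is.null(sw))
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("normality %s at %g min", g, t_final),
        method = sw$method, statistic = sw$statistic, df = sw$df,
        p = sw$p, flag = sw$flag, stringsAsFactors = FALSE)
  }
  an <- NULL
  if (length(unique(post$group)) >= 2 && length(unique(post$time_min)) >= 2) {
    an <- rm_anova_tukey(post, response = "delta_pct", between = "group",
                         within = "time_min", subject = "animal",
                         alpha = alpha)
    for (i in seq_len(nrow(an$anova)))
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste("RM-ANOVA", an$anova$effect[i]), method = "F",
        statistic = an$anova$F[i], df = an$anova$df1[i],
        p = an$anova$p[i], flag = an$anova$flag[i], stringsAsFactors = FALSE)
    gs <- unique(as.character(fin$group))
    if (length(gs) == 2) {
      tt <- t_test(fin$delta_pct[fin$group == gs[1]],
                   fin$delta_pct[fin$group == gs[2]], alpha = alpha,
                   label = sprintf("%s vs %s at %g min", gs[1], gs[2],
                                   t_final))
      rows[[length(rows) + 1L]] <- data.frame(
        label = tt$label, method = tt$method, statistic = tt$statistic,
        df = tt$df, p = tt$p, flag = tt$flag, stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- NULL
  if (!is.null(out_file)) write_tsv(comparisons, out_file)
  list(anova = an, comparisons = comparisons)
}

#' Run the whole pipeline: simulate, analyze, stats
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Root output directory; traces go to `<out_dir>/traces`,
#'   tables to `<out_dir>/results`.
#' @return The [run_stats()] result, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  tr_dir <- file.path(out_dir, "traces")
  res_dir <- file.path(out_dir, "results")
  run_simulate(config, tr_dir)
  res <- run_analyze(config, tr_dir, res_dir)
  st <- run_stats(config, res$curves,
                  out_file = file.path(res_dir, "comparisons.tsv"))
  invisible(st)
}
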