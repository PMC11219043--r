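#' Write an eye trace to disk
#'
#' One plain-text file per test: two tab-separated columns (`time_s`,
#' `position_deg`) written at full double precision, plus a YAML sidecar
#' holding the metadata (animal, group, protocol, block time, test index,
#' stimulus, and ground-truth gain when the trace is synthetic).
#'
#' @param trace An [eye_trace()].
#' @param file Output path for the trace table.
#' @param sidecar Path for the metadata sidecar (default `<file>.meta.yaml`).
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file, sidecar = paste0(file, ".meta.yaml")) {
  stopifnot(inherits(trace, "eye_trace"))
  t <- trace_time(trace)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("time_s\tposition_deg", con)
  writeLines(sprintf("%.17g\t%.17g", t, trace$position), con)
  meta <- list(
    animal = trace$meta$animal, group = trace$meta$group,
    protocol = trace$meta$protocol, time_min = trace$meta$time_min,
    test_index = trace$meta$test_index, trace_id = trace$meta$trace_id,
    rate = trace$rate, t0 = trace$t0,
    frequency = trace$stimulus$frequency,
    peak_velocity = trace$stimulus$peak_velocity,
    modality = trace$stimulus$modality,
    true_gain = if (!is.null(trace$meta$true)) trace$meta$true$gain)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  yaml::write_yaml(meta, sidecar)
  invisible(file)
}

#' Read an eye trace from disk
#'
#' Counterpart of [write_trace()].  The sampling rate is inferred from the
#' median timestep; sampling must be uniform to within 1 ppm jitter.
#'
#' @param file Trace table path.
#' @param sidecar Metadata sidecar path (default `<file>.meta.yaml`); must
#'   exist.
#' @return An [eye_trace()].
#' @export
read_trace <- function(file, sidecar = paste0(file, ".meta.yaml")) {
  if (!file.exists(file)) abort_format(sprintf("no such trace file: %s", file))
  if (!file.exists(sidecar))
    abort_format(sprintf("missing metadata sidecar: %s", sidecar))
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  if (!all(c("time_s", "position_deg") %in% names(df)) || nrow(df) < 2)
    abort_format("trace file must have columns time_s, position_deg")
  dt <- diff(df$time_s)
  med <- median(dt)
  if (med <= 0 || any(abs(dt - med) > 1e-6 * med))
    abort_format("non-uniform or non-monotone sampling beyond 1 ppm tolerance")
  meta <- yaml::read_yaml(sidecar)
  rate <- meta$rate %||% (1 / med)
  if (abs(rate * med - 1) > 1e-6)
    abort_format("sidecar rate disagrees with the file's timestep")
  spec <- if (!is.null(meta$frequency))
    stimulus_spec(meta$frequency, meta$peak_velocity,
                  modality = meta$modality %||% "vestibular")
  m <- meta[setdiff(names(meta),
                    c("rate", "t0", "frequency", "peak_velocity",
                      "modality", "true_gain"))]
  if (!is.null(meta$true_gain)) m$true <- true_state(gain = meta$true_gain)
  eye_trace(df$position_deg, rate = rate, t0 = meta$t0 %||% df$time_s[1],
            stimulus = spec, meta = m)
}
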