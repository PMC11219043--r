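#' Build the saccade/artifact exclusion mask
#'
#' Marks samples whose eye velocity deviates from the sinusoidal fit by more
#' than `threshold` (strictly; ties at the threshold are retained) as
#' saccades or movement artifacts, dilates every marked sample by `pad`
#' seconds on both sides (clipped at the trace ends), and then removes any
#' surviving retained run shorter than `min_segment` (too short to constrain
#' the refit).  The excluded fraction is computed over all samples of the
#' test, counting everything excluded for any reason.
#'
#' `rule = "excluded"` implements the alternative reading of the short-
#' segment rule: exclusion runs shorter than `min_segment` are treated as
#' noise crossings and restored instead.
#'
#' @param velocity A `"velocity_trace"` or numeric velocity vector.
#' @param fit A [fit_sinusoid()] result defining the expected waveform.
#' @param threshold Residual threshold, deg/s (default 31).
#' @param pad Dilation on each side of a marked sample, seconds (default
#'   0.050).
#' @param min_segment Minimum surviving run duration, seconds (default
#'   0.010); runs spanning exactly `min_segment` are kept.
#' @param rule Which runs the short-segment rule applies to: `"retained"`
#'   (default) or `"excluded"` (see above).
#' @param t,rate Time base when `velocity` is a bare vector.
#'
#' @return An object of class `"exclusion_mask"`: `retained` (logical per
#'   sample), `excluded_fraction`, and `segments`, a two-column matrix of
#'   half-open `[start, end)` sample index intervals exactly covering the
#'   retained samples.
#' @export
build_exclusion_mask <- function(velocity, fit, threshold = 31, pad = 0.050,
                                 min_segment = 0.010,
                                 rule = c("retained", "excluded"),
                                 t = NULL, rate = NULL) {
  rule <- match.arg(rule)
  if (inherits(velocity, "velocity_trace")) {
    v <- velocity$velocity
    rate <- velocity$rate
    t <- trace_time(velocity)
  } else {
    v <- as.numeric(velocity)
    if (is.null(rate)) abort_invalid("supply 'rate' with a bare vector")
    if (is.null(t)) t <- (seq_along(v) - 1) / rate
  }
  stopifnot(inherits(fit, "sinusoid_fit"))
  check_scalar(threshold, "threshold", nonneg = TRUE)
  check_scalar(pad, "pad", nonneg = TRUE)
  check_scalar(min_segment, "min_segment", nonneg = TRUE)
  n <- length(v)
  pad_n <- as.integer(round(pad * rate))
  min_n <- as.integer(ceiling(min_segment * rate - 1e-9))

  excl <- abs(v - predict(fit, t)) > threshold
  # dilate marked runs by pad_n samples on each side, clipped at the ends
  if (pad_n > 0L && any(excl)) {
    r <- rle(excl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      excl[max(1L, starts[i] - pad_n):min(n, ends[i] + pad_n)] <- TRUE
    }
  }
  # short-segment rule
  if (min_n > 1L) {
    r <- rle(excl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (rule == "retained") {
      for (i in which(!r$values & r$lengths < min_n))
        excl[starts[i]:ends[i]] <- TRUE
    } else {
      for (i in which(r$values & r$lengths < min_n))
        excl[starts[i]:ends[i]] <- FALSE
    }
  }
  retained <- !excl
  r <- rle(retained)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  segments <- cbind(start = starts[keep], end = ends[keep] + 1L)
  structure(list(retained = retained,
                 excluded_fraction = 1 - sum(retained) / n,
                 segments = segments),
            class = "exclusion_mask")
}

#' @export
print.exclusion_mask <- function(x, ...) {
  cat(sprintf("<exclusion_mask> %.1f%% excluded, %d retained segment(s) over %d samples\n",
              100 * x$excluded_fraction, nrow(x$segments),
              length(x$retained)))
  invisible(x)
}
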