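# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force exclusion-mask oracle: plain index arithmetic,
# one sample at a time.  Deliberately structured nothing like the rle-based
# implementation in the package.
oracle_mask <- function(resid, threshold, pad_n, min_n,
                        rule = c("retained", "excluded")) {
  rule <- match.arg(rule)
  n <- length(resid)
  marked <- logical(n)
  for (i in seq_len(n)) marked[i] <- abs(resid[i]) > threshold
  excl <- logical(n)
  for (i in seq_len(n)) {
    if (marked[i]) {
      for (j in max(1, i - pad_n):min(n, i + pad_n)) excl[j] <- TRUE
    }
  }
  # walk runs one sample at a time
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && excl[j + 1] == excl[i]) j <- j + 1
    run_len <- j - i + 1
    if (rule == "retained" && !excl[i] && run_len < min_n)
      for (k in i:j) excl[k] <- TRUE
    if (rule == "excluded" && excl[i] && run_len < min_n)
      for (k in i:j) excl[k] <- FALSE
    i <- j + 1
  }
  !excl
}

# A sinusoid fit with zero coefficients (fit to a flat trace), so that
# residuals relative to it are the velocity itself.
zero_fit <- function(duration, rate, frequency = 1) {
  fit_sinusoid(rep(0, round(duration * rate)), frequency = frequency,
               rate = rate)
}

# Clean synthetic test trace at given gain/phase/frequency.
clean_trace <- function(gain, phase = 0, frequency = 1, peak = 10,
                        duration = 45, rate = 1000) {
  synthesize_eye_trace(stimulus_spec(frequency, peak),
                       true_state(gain = gain, phase = phase),
                       duration = duration, rate = rate)
}

# Velocity-domain artifact vector supported on a sample window, made exactly
# orthogonal to the sinusoid fit basis {sin, cos, 1} so that the first-pass
# fit of (response + artifact) equals the fit of the response alone and the
# exclusion boundary can be controlled to the sample.
orthogonal_artifact <- function(n, rate, frequency, from, to, level = 200,
                                wave_hz = 5) {
  t <- (seq_len(n) - 1) / rate
  a <- numeric(n)
  a[from:to] <- level * sign(sin(2 * pi * wave_hz * (t[from:to] - t[from]) +
                                   pi / (2 * wave_hz * rate)))
  w <- 2 * pi * frequency
  X <- cbind(sin(w * t), cos(w * t), 1)
  a - X %*% solve(crossprod(X), crossprod(X, a))
}

# Ground-truth group-mean learning deltas implied by the recorded true gains
# of a simulated cohort (what a perfect measurement pipeline would recover).
true_deltas <- function(sim, baseline_time = 0) {
  meta <- unique(sim$meta[, c("animal", "group", "time_min", "true_gain")])
  parts <- split(meta, meta$animal)
  rows <- do.call(rbind, lapply(parts, function(d) {
    g0 <- d$true_gain[d$time_min == baseline_time]
    data.frame(animal = d$animal[1], group = d$group[1],
               time_min = d$time_min,
               delta_pct = 100 * (d$true_gain - g0) / g0)
  }))
  aggregate(delta_pct ~ group + time_min, rows, mean)
}

# Measures a simulated cohort and returns group-mean recovered deltas merged
# with the ground-truth deltas.
recovered_vs_true <- function(sim, ...) {
  res <- analyze_cohort(sim, ...)
  rec <- aggregate(delta_pct ~ group + time_min, res$curves, mean)
  tru <- true_deltas(sim)
  merge(rec, tru, by = c("group", "time_min"),
        suffixes = c("_recovered", "_true"))
}
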