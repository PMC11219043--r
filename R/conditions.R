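# Classed conditions so callers can distinguish failure modes programmatically.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vorlearn_error", "error"),
                      call = NULL))
}

abort_invalid <- function(msg) abort(msg, "vorlearn_invalid_argument")
abort_degenerate <- function(msg) abort(msg, "vorlearn_degenerate_fit")
abort_format <- function(msg) abort(msg, "vorlearn_format_error")
abort_missing_baseline <- function(msg) abort(msg, "vorlearn_missing_baseline")
abort_empty_results <- function(msg) abort(msg, "vorlearn_empty_results")

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards; seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_invalid("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Small helper used by several validators.
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    abort_invalid(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0)
    abort_invalid(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
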