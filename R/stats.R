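#' @importFrom stats aov pf shapiro.test t.test as.formula coef predict
#'   median complete.cases
NULL

stat_result <- function(label, statistic, df, p, method, alpha = 0.05,
                        note = NULL) {
  structure(list(label = label, statistic = statistic, df = df, p = p,
                 flag = is.finite(p) && p < alpha, alpha = alpha,
                 method = method, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: %s = %.4g (df %s), p = %.4g%s\n", x$label, x$method,
              x$statistic, dfs, x$p,
              if (x$flag) " *" else ""))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Normality check applied to each sample before the parametric
#' comparisons.  A non-normal result is reported, not acted upon (the
#' parametric tests are still run, matching common practice for these
#' designs).
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @param alpha Significance level (default 0.05).
#' @return A `"stat_result"` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    abort_invalid("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0)
    abort_degenerate("sample has zero variance")
  sw <- shapiro.test(values)
  stat_result("normality", unname(sw$statistic), n, sw$p.value,
              "Shapiro-Wilk W", alpha)
}

#' Two-sample or paired t-test
#'
#' Standard two-sided t-test: two-sample (pooled variance) or paired.  The
#' degenerate paired case of identical samples (zero variance of the
#' differences) is reported as statistic 0 with p = 1 by convention.
#'
#' @param a,b Numeric samples (equal length when paired).
#' @param paired Paired test? (default `FALSE`).
#' @param var_equal Pool variances in the two-sample case (default `TRUE`,
#'   the classical two-sample t-test).
#' @param alpha Significance level.
#' @param label Comparison label carried into the result.
#' @return A `"stat_result"`.
#' @examples
#' t_test(c(1, 2, 4), c(2, 3, 4), paired = TRUE)  # t = -2
#' @export
t_test <- function(a, b, paired = FALSE, var_equal = TRUE, alpha = 0.05,
                   label = if (paired) "paired" else "two-sample") {
  if (length(a) < 2 || length(b) < 2)
    abort_invalid("each sample needs n >= 2")
  if (paired && length(a) != length(b))
    abort_invalid("paired samples must have equal length")
  res <- tryCatch(
    t.test(a, b, paired = paired, var.equal = var_equal),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic)) {
    return(stat_result(label, 0, length(a) - 1, 1,
                       if (paired) "paired t" else "two-sample t", alpha,
                       note = "zero-variance differences; p = 1 by convention"))
  }
  stat_result(label, unname(res$statistic), unname(res$parameter),
              res$p.value, if (paired) "paired t" else "two-sample t", alpha)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x within-level response matrix.
gg_epsilon <- function(Y, groups) {
  k <- ncol(Y)
  if (k < 3) return(1)
  E <- Y
  for (g in unique(groups)) {
    idx <- groups == g
    E[idx, ] <- sweep(Y[idx, , drop = FALSE], 2,
                      colMeans(Y[idx, , drop = FALSE]))
  }
  S <- crossprod(E) / max(1L, nrow(Y) - length(unique(groups)))
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))                       # orthonormal contrasts, k x (k-1)
  M <- t(C) %*% S %*% C
  tr <- sum(diag(M))
  denom <- (k - 1) * sum(M^2)
  if (denom <= 0) return(1)
  min(1, max(1 / (k - 1), tr^2 / denom))
}

#' Two-factor repeated-measures ANOVA with Tukey contrasts
#'
#' Univariate repeated-measures ANOVA with one between-subject factor
#' (group) and one within-subject factor (time), fit with [stats::aov()]
#' and `Error(subject/time)` strata, followed by Tukey-adjusted pairwise
#' contrasts among all group x time cell means (via \pkg{emmeans}).  The
#' contrast family is the full set of cells, the common convention.
#'
#' Subjects missing any within-factor level are dropped with a warning.
#' Sphericity is not assumed silently: the Greenhouse-Geisser corrected
#' p-values for the within effects are reported alongside the uncorrected
#' ones (`p_gg`); significance is flagged on the uncorrected p by default.
#'
#' @param data Data frame in long format.
#' @param response,between,within,subject Column names (defaults
#'   `"delta_pct"`, `"group"`, `"time_min"`, `"animal"`).
#' @param alpha Significance level (default 0.05).
#' @param tukey Also compute the Tukey contrasts? (default `TRUE`).
#' @return Object of class `"rm_anova"`: `anova` (data frame with effect,
#'   df, F, p, p_gg, flag), `tukey` (data frame of pairwise contrasts with
#'   Tukey-adjusted p), `epsilon` (Greenhouse-Geisser), `dropped` (subjects
#'   removed as incomplete).
#' @export
rm_anova_tukey <- function(data, response = "delta_pct", between = "group",
                           within = "time_min", subject = "animal",
                           alpha = 0.05, tukey = TRUE) {
  stopifnot(is.data.frame(data))
  for (col in c(response, between, within, subject))
    if (!col %in% names(data))
      abort_invalid(sprintf("column '%s' not found", col))
  d <- data.frame(y = data[[response]],
                  g = factor(data[[between]]),
                  t = factor(data[[within]]),
                  s = factor(data[[subject]]))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$g)) < 2)
    abort_invalid("between factor needs at least 2 levels")
  if (nlevels(droplevels(d$t)) < 2)
    abort_invalid("within factor needs at least 2 levels")
  # drop subjects not observed at every within level
  tab <- table(d$s, d$t)
  complete <- rownames(tab)[apply(tab >= 1, 1, all)]
  dropped <- setdiff(levels(d$s), complete)
  if (length(dropped))
    warning(sprintf("dropping incomplete subject(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  d <- droplevels(d[d$s %in% complete, , drop = FALSE])
  if (!nrow(d)) abort_invalid("no complete subjects left")

  # sum-to-zero contrasts up front: emmeans would otherwise refit the
  # aovlist itself, which re-evaluates the call in the wrong environment
  fit <- aov(y ~ g * t + Error(s / t), data = d,
             contrasts = list(g = "contr.sum", t = "contr.sum"))
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    labs <- trimws(rownames(st))
    for (i in seq_along(labs)) {
      if (labs[i] == "Residuals") next
      effect <- switch(labs[i], g = between, t = within,
                       `g:t` = paste0(between, ":", within), labs[i])
      rows[[effect]] <- data.frame(
        effect = effect, df1 = st[i, "Df"],
        df2 = st[nrow(st), "Df"], F = st[i, "F value"],
        p = st[i, "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }
  an <- do.call(rbind, rows)
  rownames(an) <- NULL

  # Greenhouse-Geisser correction for the within effects
  wide <- tapply(d$y, list(d$s, d$t), mean)
  grp_of <- tapply(as.character(d$g), d$s, function(x) x[1])
  eps <- gg_epsilon(wide, grp_of[rownames(wide)])
  an$p_gg <- an$p
  wi <- an$effect %in% c(within, paste0(between, ":", within))
  an$p_gg[wi] <- pf(an$F[wi], eps * an$df1[wi], eps * an$df2[wi],
                    lower.tail = FALSE)
  an$flag <- an$p < alpha

  tk <- NULL
  if (tukey) {
    emm <- emmeans::emmeans(fit, specs = ~ g * t, data = d)
    tk <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise",
                                                  adjust = "tukey")))
    names(tk)[names(tk) == "p.value"] <- "p"
    # pairwise contrasts come in combn() order over the grid rows
    grid <- summary(emm)
    cells <- paste(grid$g, grid$t)
    pr <- utils::combn(cells, 2)
    tk$cell1 <- pr[1, ]
    tk$cell2 <- pr[2, ]
    tk$flag <- tk$p < alpha
  }
  structure(list(anova = an, tukey = tk, epsilon = eps, dropped = dropped,
                 alpha = alpha,
                 factors = list(response = response, between = between,
                                within = within, subject = subject)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$factors$between, " x ",
      x$factors$within, ")\n", sep = "")
  an <- x$anova
  an$F <- signif(an$F, 4)
  an$p <- signif(an$p, 4)
  an$p_gg <- signif(an$p_gg, 4)
  print(an, row.names = FALSE)
  cat(sprintf("Greenhouse-Geisser epsilon = %.3f\n", x$epsilon))
  if (length(x$dropped))
    cat("Dropped incomplete subjects:", paste(x$dropped, collapse = ", "),
        "\n")
  if (!is.null(x$tukey)) {
    sig <- x$tukey[x$tukey$flag, , drop = FALSE]
    cat(sprintf("Tukey: %d of %d cell contrasts significant at alpha = %g\n",
                nrow(sig), nrow(x$tukey), x$alpha))
  }
  invisible(x)
}

#' Extract one Tukey contrast
#'
#' Finds the Tukey contrast between two group x time cells in an
#' [rm_anova_tukey()] result, e.g. the within-group 0 vs 30 min comparison.
#'
#' @param x An `"rm_anova"`.
#' @param cell1,cell2 Cell labels as `"group time"` (the emmeans naming,
#'   e.g. `"WT 30"`).
#' @return One-row data frame, or an error if not found.
#' @export
tukey_contrast <- function(x, cell1, cell2) {
  stopifnot(inherits(x, "rm_anova"))
  if (is.null(x$tukey)) abort_invalid("no Tukey table in this result")
  hit <- (x$tukey$cell1 == cell1 & x$tukey$cell2 == cell2) |
    (x$tukey$cell1 == cell2 & x$tukey$cell2 == cell1)
  if (!any(hit))
    abort_invalid(sprintf("contrast %s vs %s not found", cell1, cell2))
  x$tukey[which(hit)[1], , drop = FALSE]
}
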