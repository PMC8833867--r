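# Cohort descriptive statistics and the enzyme-assay analysis: one-way
# ANOVA across timepoints with Tukey HSD post-hoc comparisons.

#' Descriptive statistics of a numeric vector
#'
#' Reports n, mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum; `format_descriptives()` renders the conventional
#' one-decimal `mean +/- SD (range)` string.
#'
#' @param values Numeric vector (non-empty; n >= 2 for a standard
#'   deviation).
#' @return A list of class `descriptive_stats` with fields `n`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop_input("values must be a non-empty vector of finite numbers")
  }
  structure(list(n = length(values), mean = mean(values),
                 sd = if (length(values) >= 2L) sd(values) else NA_real_,
                 min = min(values), max = max(values)),
            class = "descriptive_stats")
}

#' @rdname descriptive_stats
#' @param stats A `descriptive_stats` object.
#' @param digits Decimal places for formatting (default 1).
#' @export
format_descriptives <- function(stats, digits = 1L) {
  stopifnot(inherits(stats, "descriptive_stats"))
  sprintf("%.*f ± %.*f (range = %.*f–%.*f)",
          digits, stats$mean, digits, stats$sd,
          digits, stats$min, digits, stats$max)
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, sd = %.4g, range = [%.4g, %.4g]\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

assay_groups <- function(assay) {
  assay <- validate_assay_table(assay)
  groups <- split(assay$activity, assay$timepoint_minutes)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop_input("every timepoint group needs at least 2 observations")
  }
  groups
}

#' One-way ANOVA of activity across timepoints
#'
#' Classic between/within sum-of-squares decomposition, fitted through
#' `stats::aov` with the timepoint as a factor.  Replicates are treated as
#' independent observations within their timepoint group.  Two degenerate
#' inputs are defined by contract: when both sums of squares are zero
#' (all values equal) the result is `F = 0, p = 1`; when the within-group
#' variance is zero but group means differ, `p = 0` is reported with a
#' warning.
#'
#' @param assay Assay table (data frame with `animal_id`,
#'   `timepoint_minutes`, `replicate`, `activity`).
#' @return A list of class `anova_result` with `f`, `df_between`,
#'   `df_within`, `p`.
#' @export
one_way_anova <- function(assay) {
  groups <- assay_groups(assay)
  k <- length(groups)
  n <- sum(lengths(groups))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  grand <- mean(unlist(groups))
  ss_between <- sum(lengths(groups) *
                      (vapply(groups, mean, numeric(1L)) - grand)^2)
  out <- list(f = NA_real_, df_between = k - 1L, df_within = n - k, p = NA_real_)
  if (ss_within <= .Machine$double.eps * max(1, ss_between)) {
    if (ss_between <= .Machine$double.eps) {
      out$f <- 0; out$p <- 1
    } else {
      warning("zero within-group variance with distinct means: p reported as 0",
              call. = FALSE)
      out$f <- Inf; out$p <- 0
    }
    return(structure(out, class = "anova_result"))
  }
  df <- data.frame(activity = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  fit <- anova(aov(activity ~ group, data = df))
  out$f <- fit$`F value`[1L]
  out$p <- fit$`Pr(>F)`[1L]
  structure(out, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

#' Tukey HSD post-hoc comparisons across timepoints
#'
#' All pairwise comparisons of timepoint group means.  For groups i, j the
#' studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer form, exact for balanced groups); the adjusted p-value
#' comes from the studentized-range distribution with (k, df_within)
#' parameters, and the confidence interval half-width is
#' `q_crit * sqrt(MS_within / 2 * (1/n_i + 1/n_j))` at level `1 - alpha`.
#'
#' @param assay Assay table, as for [one_way_anova()].
#' @param alpha Family-wise error level in (0, 1) (default 0.05).
#' @return A data frame with one row per group pair: `group_i`, `group_j`,
#'   `diff` (mean_j - mean_i), `q`, `p_adj`, `lwr`, `upr`.
#' @export
tukey_hsd <- function(assay, alpha = 0.05) {
  if (!is_real_scalar(alpha) || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must lie strictly between 0 and 1")
  }
  groups <- assay_groups(assay)
  k <- length(groups)
  sizes <- lengths(groups)
  means <- vapply(groups, mean, numeric(1L))
  df_within <- sum(sizes) - k
  ms_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1L))) / df_within
  pairs <- utils::combn(k, 2L)
  q_crit <- qtukey(1 - alpha, k, df_within)
  rows <- apply(pairs, 2L, function(idx) {
    i <- idx[1L]; j <- idx[2L]
    se <- sqrt(ms_within / 2 * (1 / sizes[i] + 1 / sizes[j]))
    diff <- means[j] - means[i]
    if (se > 0) {
      q <- abs(diff) / se
      # for two groups the studentized range reduces exactly to the
      # two-sided t distribution; use the closed form there rather than the
      # general quadrature, whose absolute error is around 1e-8
      p <- if (k == 2L) {
        2 * pt(q / sqrt(2), df_within, lower.tail = FALSE)
      } else {
        ptukey(q, k, df_within, lower.tail = FALSE)
      }
      half <- q_crit * se
    } else {
      q <- if (abs(diff) > 0) Inf else 0
      p <- if (abs(diff) > 0) 0 else 1
      half <- 0
    }
    data.frame(group_i = names(groups)[i], group_j = names(groups)[j],
               diff = unname(diff), q = unname(q), p_adj = unname(p),
               lwr = unname(diff - half), upr = unname(diff + half),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
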