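#' Exact McNemar test on discordant pair counts
#'
#' Exact two-sided McNemar test for paired binary outcomes, as a binomial
#' test on the discordant pairs: with `b` pairs discordant in one
#' direction and `c` in the other,
#' \deqn{p = \min\left(1,\; 2 \sum_{k \le \min(b, c)}
#'   \binom{b + c}{k} 0.5^{\,b + c}\right).}
#' The exact (not chi-square) form is the one appropriate for the small
#' discordance counts of a 12-animal cohort.  With no discordant pairs at
#' all the data carry no information about a difference and `p = 1` is
#' returned with a warning.
#'
#' @param discordant_ab Number of pairs with outcome A only.
#' @param discordant_ba Number of pairs with outcome B only.
#' @return A tibble: `statistic` (the smaller discordant count),
#'   `n_discordant`, `p.value`, `method`.
#' @examples
#' mcnemar_exact(7, 0)  # p = 0.015625
#' mcnemar_exact(6, 0)  # p = 0.03125
#' @export
mcnemar_exact <- function(discordant_ab, discordant_ba) {
  b <- discordant_ab
  c_ <- discordant_ba
  if (length(b) != 1 || length(c_) != 1 || !is.finite(b) || !is.finite(c_) ||
      b < 0 || c_ < 0 || b != round(b) || c_ != round(c_)) {
    stop_input("Discordant counts must be single non-negative integers.")
  }
  n <- b + c_
  if (n == 0) {
    warn("No discordant pairs: McNemar test is uninformative; p = 1 by convention.")
    p <- 1
  } else {
    p <- min(1, 2 * pbinom(min(b, c_), n, 0.5))
  }
  tibble(statistic = min(b, c_), n_discordant = n, p.value = p,
         method = "exact McNemar (binomial)")
}

#' Discordant pairs from nested success counts
#'
#' Reconstructs the discordant cells of a paired 2x2 success table from
#' marginal success counts under the nesting assumption that no animal
#' succeeded at the weaker setting while failing at the stronger one
#' (the only structure consistent with success rates that increase with
#' energy in the same animals).  With successes `s_a <= s_b` out of `n`
#' pairs, the discordance is then `(s_b - s_a, 0)`.
#'
#' @param success_a,success_b Success counts under the two conditions.
#' @param n Number of pairs (same animals under both conditions).
#' @return A named vector `c(ab = ..., ba = ...)` of discordant counts,
#'   where `ab` counts pairs succeeding only under the condition with the
#'   higher success count.
#' @examples
#' nested_discordance(5, 12, 12)  # c(ab = 7, ba = 0)
#' @export
nested_discordance <- function(success_a, success_b, n) {
  if (success_a < 0 || success_b < 0 || success_a > n || success_b > n) {
    stop_input("Success counts must lie in [0, n].")
  }
  c(ab = abs(success_b - success_a), ba = 0)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject analysis of variance for a complete subjects x
#' conditions layout, computed from explicit sums of squares:
#' \deqn{SS_{cond} = n \sum_c (\bar y_{\cdot c} - \bar y)^2, \quad
#'       SS_{subj} = k \sum_s (\bar y_{s \cdot} - \bar y)^2, \quad
#'       SS_{err} = SS_{tot} - SS_{cond} - SS_{subj},}
#' with \eqn{F = MS_{cond} / MS_{err}} on \eqn{(k - 1, (k - 1)(n - 1))}
#' degrees of freedom.  Sphericity is assumed by default (with k = 3
#' closely spaced conditions the correction is minor); setting
#' `gg_correction = TRUE` applies the Greenhouse--Geisser epsilon to the
#' degrees of freedom.
#'
#' @param data A data frame in long format.
#' @param value,subject,condition Column names (unquoted or character) of
#'   the measurement, subject id and within-subject condition.
#' @param gg_correction Apply the Greenhouse--Geisser sphericity
#'   correction to the degrees of freedom (default `FALSE`).
#'
#' @return An object of class `rm_anova`; see [tidy.rm_anova()] and
#'   [glance.rm_anova()].
#' @examples
#' d <- tidyr::expand_grid(pig = factor(1:6), cond = factor(c("a", "b", "c")))
#' d$y <- rnorm(nrow(d))
#' rm_anova(d, y, pig, cond)
#' @export
rm_anova <- function(data, value, subject, condition, gg_correction = FALSE) {
  value <- rlang::as_name(rlang::enquo(value))
  subject <- rlang::as_name(rlang::enquo(subject))
  condition <- rlang::as_name(rlang::enquo(condition))
  d <- tibble(
    y = as.numeric(data[[value]]),
    s = as.character(data[[subject]]),
    c = as.character(data[[condition]])
  )
  if (any(is.na(d$y))) stop_input("Missing measurements: the default analysis needs a complete matrix.")
  wide <- tidyr::pivot_wider(d, names_from = "c", values_from = "y")
  y <- as.matrix(wide[, -1])
  if (any(is.na(y))) {
    stop_input("Unbalanced design: every subject needs exactly one value per condition.")
  }
  n <- nrow(y)  # subjects
  k <- ncol(y)  # conditions
  if (n < 2 || k < 2) stop_input("Need at least 2 subjects and 2 conditions.")

  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df_cond <- k - 1
  df_err <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df_cond
  ms_err <- ss_err / df_err
  # ss_err is a difference of large sums; treat anything at rounding scale
  # relative to the total variation as exactly zero.
  if (ss_err <= 1e-10 * max(ss_total, .Machine$double.xmin)) {
    stop_numerical("Zero within-subject error variance: degenerate design for an F test.")
  }
  f <- ms_cond / ms_err

  eps <- gg_epsilon(y)
  if (gg_correction) {
    p <- pf(f, eps * df_cond, eps * df_err, lower.tail = FALSE)
    df_used <- c(eps * df_cond, eps * df_err)
  } else {
    p <- pf(f, df_cond, df_err, lower.tail = FALSE)
    df_used <- c(df_cond, df_err)
  }

  structure(
    list(
      statistic = f, df = df_used, p.value = p,
      ss = c(conditions = ss_cond, subjects = ss_subj, error = ss_err,
             total = ss_total),
      ms = c(conditions = ms_cond, error = ms_err),
      n_subjects = n, n_conditions = k,
      gg_epsilon = eps, gg_correction = gg_correction,
      condition_means = colMeans(y)
    ),
    class = "rm_anova"
  )
}

# Greenhouse-Geisser epsilon from the sample covariance of the condition
# columns (double-centred covariance eigen-structure form).
gg_epsilon <- function(y) {
  k <- ncol(y)
  S <- stats::cov(y)
  Sc <- S - outer(rowMeans(S), colMeans(S), "+") + mean(S)
  tr <- sum(diag(Sc))
  eps <- tr^2 / ((k - 1) * sum(Sc^2))
  min(1, max(eps, 1 / (k - 1)))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("One-way repeated-measures ANOVA\n")
  cat(sprintf("  %d subjects x %d conditions\n", x$n_subjects, x$n_conditions))
  cat(sprintf("  F(%.4g, %.4g) = %.4g, p = %.3f%s\n",
              x$df[1], x$df[2], x$statistic, x$p.value,
              if (x$gg_correction) sprintf(" (Greenhouse-Geisser eps = %.3f)", x$gg_epsilon) else ""))
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per source of variation (`conditions`,
#'   `subjects`, `error`): sums of squares, df, mean squares, F and p
#'   where defined.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) {
  n <- x$n_subjects
  k <- x$n_conditions
  tibble(
    term = c("conditions", "subjects", "error"),
    sumsq = unname(x$ss[c("conditions", "subjects", "error")]),
    df = c(k - 1, n - 1, (k - 1) * (n - 1)),
    meansq = c(x$ms[["conditions"]], x$ss[["subjects"]] / (n - 1), x$ms[["error"]]),
    statistic = c(x$statistic, NA_real_, NA_real_),
    p.value = c(x$p.value, NA_real_, NA_real_)
  )
}

#' Glance at a repeated-measures ANOVA
#'
#' @inheritParams tidy.rm_anova
#' @return A one-row tibble: `statistic`, `df`, `df.residual`, `p.value`,
#'   `gg.epsilon`, `n.subjects`, `n.conditions`.
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df[1], df.residual = x$df[2],
    p.value = x$p.value, gg.epsilon = x$gg_epsilon,
    n.subjects = x$n_subjects, n.conditions = x$n_conditions
  )
}

#' Paired contrast between two within-subject measurements
#'
#' Paired t procedure on per-subject differences `d = x - y`: mean
#' difference, its two-sided `conf_level` confidence interval
#' \eqn{\bar d \pm t_{1-\alpha/2, n-1}\, s_d/\sqrt{n}}, and the two-sided
#' p-value.  If every difference is identical the interval collapses to a
#' point and the result is flagged `degenerate`.
#'
#' @param x,y Numeric vectors of per-subject values, same subjects in the
#'   same order.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `statistic`, `df`, `p.value`, `degenerate`.
#' @examples
#' paired_contrast(c(5, 6, 7), c(4, 5, 6))
#' @export
paired_contrast <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop_input("`x` and `y` must have equal length (same subjects).")
  if (length(x) < 2) stop_input("Need at least 2 pairs.")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_input("Values must be finite.")
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    warn("All paired differences are identical: zero-variance contrast; CI collapses to a point.")
    return(tibble(estimate = m, conf.low = m, conf.high = m,
                  statistic = NA_real_, df = n - 1,
                  p.value = if (m == 0) 1 else 0, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  tstat <- m / se
  tc <- qt(1 - (1 - conf_level) / 2, n - 1)
  tibble(
    estimate = m, conf.low = m - tc * se, conf.high = m + tc * se,
    statistic = tstat, df = n - 1,
    p.value = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE),
    degenerate = FALSE
  )
}

#' Ratio of single-application to serial threshold means
#'
#' Mean of the two single-application group thresholds divided by the
#' serial-application threshold; the conventional report rounds it to one
#' decimal.
#'
#' @param single_means Numeric vector of the two single-application group
#'   means (A/cm\eqn{^2}).
#' @param serial_mean Serial-group mean (A/cm\eqn{^2}), > 0.
#' @return The unrounded ratio.
#' @examples
#' threshold_ratio(c(4.3, 5.1), 3.4)  # ~ 1.4
#' @export
threshold_ratio <- function(single_means, serial_mean) {
  if (length(serial_mean) != 1 || !is.finite(serial_mean) || serial_mean <= 0) {
    stop_domain("`serial_mean` must be a single positive value.")
  }
  if (any(!is.finite(single_means))) stop_input("`single_means` must be finite.")
  mean(single_means) / serial_mean
}
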