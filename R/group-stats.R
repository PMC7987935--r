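# Inferential layer: Bonferroni-corrected two-sample t-tests across a
# variable family, Pearson chi-squared tests on 2 x k tables, and
# Bland-Altman agreement between actigraphy-derived and diary-reported
# sleep durations.

#' Bonferroni-corrected two-sample t-tests over a variable family
#'
#' Runs a two-sample t-test per variable between two groups and flags
#' significance at the Bonferroni-corrected level `alpha / m`, where `m` is
#' the family size (e.g. 0.05/40 = 0.00125 for the actigraphy battery,
#' 0.05/13 = 0.0038 for the questionnaire totals). The default is Student's
#' pooled-variance test; set `var_equal = FALSE` for Welch.
#'
#' @param data data frame holding the variables.
#' @param group logical vector (or name of a logical column in `data`)
#'   splitting the rows into two groups.
#' @param vars variable names to compare (default: all numeric columns
#'   except the group column).
#' @param m family size for the correction (default `length(vars)`).
#' @param alpha family-wise significance level.
#' @param var_equal pooled-variance (Student) test if `TRUE`.
#' @return A data frame of class `comparison_report` with one row per
#'   variable: group means and sds, `t`, `p`, and `significant`
#'   (`p < alpha / m`). The threshold is stored in attribute `threshold`.
#' @export
ttest_bonferroni <- function(data, group, vars = NULL, m = NULL,
                             alpha = 0.05, var_equal = TRUE) {
  if (is.character(group) && length(group) == 1L) {
    group_name <- group
    group <- data[[group]]
  } else {
    group_name <- NULL
  }
  group <- as.logical(group)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, group_name)
  }
  if (is.null(m)) m <- length(vars)
  threshold <- alpha / m
  rows <- lapply(vars, function(v) {
    a <- data[[v]][group & !is.na(data[[v]])]
    b <- data[[v]][!group & !is.na(data[[v]])]
    if (length(a) < 2L || length(b) < 2L) {
      stop("variable `", v, "`: both groups need n >= 2", call. = FALSE)
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
    }
    data.frame(
      variable = v,
      mean_g1 = mean(a), sd_g1 = stats::sd(a), n_g1 = length(a),
      mean_g2 = mean(b), sd_g2 = stats::sd(b), n_g2 = length(b),
      t = unname(tt$statistic), p = tt$p.value,
      significant = tt$p.value < threshold
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Pearson chi-squared test on a 2 x k table
#'
#' Pearson's chi-squared test of independence without continuity
#' correction; for a 2 x k table the degrees of freedom are `k - 1`.
#'
#' @param table a 2 x k matrix of counts (rows = groups, columns =
#'   categories).
#' @return A list with `chi2`, `df`, `p` and the `expected` counts.
#' @export
chi2_2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop("expected a 2 x k table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value,
    expected = ct$expected
  )
}

#' Bland-Altman agreement between paired measurements
#'
#' For paired measurements (e.g. actigraphy-derived vs diary-reported sleep
#' duration per night), computes the per-pair differences `x - y`, their
#' mean (bias) and the 95% limits of agreement `bias +/- 1.96 sd`.
#'
#' @param x,y paired numeric measurements (first minus second defines the
#'   difference).
#' @return A list of class `agreement_report`: `bias`, `sd_diff`,
#'   `lower`, `upper`, `n`, and the `differences` and `means` used for the
#'   standard Bland-Altman plot.
#' @export
bland_altman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      bias = bias, sd_diff = s,
      lower = bias - 1.96 * s, upper = bias + 1.96 * s,
      n = length(d), differences = d, means = (x + y) / 2
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d pairs): bias %.1f min, 95%% limits [%.1f, %.1f]\n",
    x$n, x$bias, x$lower, x$upper
  ))
  invisible(x)
}
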