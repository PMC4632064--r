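# Effect-size estimation (Cohen's d) and two-sample t-test power
# projection via the noncentral t distribution.

#' Cohen's d from two groups
#'
#' Standardized mean difference `(mean_case - mean_control) / s_pooled`,
#' with the df-weighted pooled standard deviation. Sign convention:
#' case minus control.
#'
#' @param case_values,control_values Numeric vectors (>= 2 each).
#' @return List with `d`, `pooled_sd`, `n_case`, `n_control`, `undefined`
#'   (TRUE when the pooled SD is zero).
#' @export
cohens_d <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  stopifnot(n1 >= 2L, n2 >= 2L)
  sp <- sqrt(((n1 - 1) * var(case_values) + (n2 - 1) * var(control_values)) /
               (n1 + n2 - 2))
  if (sp == 0) {
    return(list(d = NA_real_, pooled_sd = 0, n_case = n1, n_control = n2,
                undefined = TRUE))
  }
  list(d = (mean(case_values) - mean(control_values)) / sp, pooled_sd = sp,
       n_case = n1, n_control = n2, undefined = FALSE)
}

#' Power of the two-sample t test at a given effect size
#'
#' Exact noncentral-t computation for equal group sizes: with
#' noncentrality `delta = d * sqrt(n^2 / (2n))` and `df = 2n - 2`, power is
#' the probability that the noncentral t exceeds the critical value (both
#' tails for the two-sided test).
#'
#' @param d Cohen's d (signed).
#' @param n_per_group Subjects per group (>= 2).
#' @param alpha Significance level in (0, 0.5]; default 0.05.
#' @param sided `"one"` (default, direction of `d`) or `"two"`.
#' @return List with `d`, `n_per_group`, `alpha`, `sided`, `noncentrality`,
#'   `df`, `power`.
#' @export
power_two_sample_t <- function(d, n_per_group, alpha = 0.05,
                               sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(n_per_group >= 2L, alpha > 0, alpha <= 0.5)
  n1 <- n_per_group; n2 <- n_per_group
  df <- n1 + n2 - 2L
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (sided == "one") {
    tcrit <- qt(1 - alpha, df)
    pw <- pt(tcrit, df, ncp = abs(ncp), lower.tail = FALSE)
  } else {
    tcrit <- qt(1 - alpha / 2, df)
    pw <- pt(tcrit, df, ncp = abs(ncp), lower.tail = FALSE) +
      pt(-tcrit, df, ncp = abs(ncp))
  }
  list(d = d, n_per_group = n_per_group, alpha = alpha, sided = sided,
       noncentrality = ncp, df = df, power = pw)
}

#' Power table over effect sizes and sample sizes
#'
#' Cross-product of labelled effect sizes and a grid of per-group sample
#' sizes.
#'
#' @param effect_sizes Named numeric vector of Cohen's d values (names are
#'   row labels).
#' @param n_grid Integer vector of per-group sample sizes.
#' @param alpha,sided Passed to [power_two_sample_t()].
#' @return data.frame with `label`, `d`, `n_per_group`, `alpha`, `sided`,
#'   `power`.
#' @export
power_table <- function(effect_sizes, n_grid, alpha = 0.05,
                        sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (!length(effect_sizes)) {
    return(data.frame(label = character(), d = numeric(),
                      n_per_group = integer(), alpha = numeric(),
                      sided = character(), power = numeric(),
                      stringsAsFactors = FALSE))
  }
  labels <- names(effect_sizes) %||% as.character(effect_sizes)
  if (is.null(names(effect_sizes))) names(effect_sizes) <- labels
  grid <- expand.grid(label = names(effect_sizes), n_per_group = n_grid,
                      stringsAsFactors = FALSE)
  grid$d <- effect_sizes[grid$label]
  grid$alpha <- alpha
  grid$sided <- sided
  grid$power <- mapply(function(d, n) {
    power_two_sample_t(d, n, alpha, sided)$power
  }, grid$d, grid$n_per_group)
  grid[, c("label", "d", "n_per_group", "alpha", "sided", "power")]
}
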