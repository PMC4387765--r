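#' Group summary: n, mean and SEM
#'
#' Results are reported as mean +/- SEM, with SEM the sample standard
#' deviation (n - 1 denominator) divided by sqrt(n); SEM is NA for n = 1.
#'
#' @param values numeric vector (n >= 1).
#' @param condition optional condition label(s).
#' @param metric optional name of the measurement.
#' @return object of class `group_summary` (one-row data.frame with
#'   columns condition, metric, n, mean, sem).
#' @export
group_summary <- function(values, condition = NA_character_,
                          metric = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L)
    stop_fiberflux("fiberflux_empty_group", "no values to summarize")
  out <- data.frame(condition = paste(unlist(condition), collapse = "_"),
                    metric = metric, n = n, mean = mean(values),
                    sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic pooled-variance two-sample t-test with a two-tailed p-value on
#' n_a + n_b - 2 degrees of freedom, plus the star annotation. When both
#' groups are constant and equal the comparison is degenerate and returns
#' t = 0, p = 1.
#'
#' @param a,b numeric vectors, each with n >= 2.
#' @param label_a,label_b optional group labels.
#' @return object of class `comparison`: one-row data.frame with columns
#'   group_a, group_b, n_a, n_b, mean_a, mean_b, t_stat, df, p_value,
#'   stars.
#' @export
two_sample_ttest <- function(a, b, label_a = "a", label_b = "b") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_fiberflux("fiberflux_small_group",
                   "each group needs n >= 2 (got %d and %d)", length(a), length(b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    t_stat <- 0; p <- 1; df <- length(a) + length(b) - 2
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    t_stat <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  out <- data.frame(group_a = label_a, group_b = label_b,
                    n_a = length(a), n_b = length(b),
                    mean_a = mean(a), mean_b = mean(b),
                    t_stat = t_stat, df = df, p_value = p,
                    stars = significance_stars(p))
  class(out) <- c("comparison", "data.frame")
  out
}

#' Significance star annotation
#'
#' `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.05, `""` otherwise
#' (strict inequalities, so p = 0.05 gets no star).
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_fiberflux("fiberflux_bad_p", "p-values must lie in [0, 1]")
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}
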