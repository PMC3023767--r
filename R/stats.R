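#' Geometric mean
#'
#' `exp(mean(log(x)))`; all values must be positive. Satisfies
#' `geometric_mean(lambda * x) == lambda * geometric_mean(x)`.
#'
#' @param x positive numeric vector.
#' @return length-1 numeric.
#' @export
#' @examples
#' geometric_mean(c(10, 100, 1000))  # 100
geometric_mean <- function(x) {
  check_finite(x, "x")
  if (any(x <= 0)) abort2("geometric mean needs positive values",
                          "acidhesion_bad_arg")
  exp(mean(log(x)))
}

#' Normalized geometric mean fluorescence intensity
#'
#' Ratio of the mean of the test cell line's per-replicate geometric MFIs to
#' the mean of the receptor-negative control line's, the quantity used to
#' compare antibody binding across conditions independently of staining
#' batch.
#'
#' @param test,control positive per-replicate geometric MFI values.
#' @return length-1 numeric ratio.
#' @export
normalized_geometric_mfi <- function(test, control) {
  check_finite(test, "test"); check_finite(control, "control")
  if (any(test <= 0) || any(control <= 0)) {
    abort2("MFI values must be positive", "acidhesion_bad_arg")
  }
  m <- mean(control)
  mean(test) / m
}

#' Express values relative to a reference condition's mean
#'
#' Divides every value by the mean of the reference condition, so the
#' reference condition's mean becomes exactly 1. Invariant under a common
#' rescaling of all inputs.
#'
#' @param values numeric vector.
#' @param condition condition label per value.
#' @param reference reference condition label.
#' @return numeric vector of the same length.
#' @export
relative_to_reference <- function(values, condition, reference) {
  check_finite(values, "values")
  if (length(values) != length(condition)) {
    abort2("values and condition must have equal length",
           "acidhesion_bad_arg")
  }
  ref <- values[condition == reference]
  if (!length(ref)) abort2("reference condition absent",
                           "acidhesion_bad_arg")
  m <- mean(ref)
  if (m == 0) abort2("reference mean is zero", "acidhesion_bad_arg")
  values / m
}

#' Unpaired two-sample t-test
#'
#' Classical pooled-variance (Student) t by default, the conventional
#' "unpaired t-test" of biology statistics packages; Welch's unequal-variance
#' form is available behind `welch = TRUE`. Two-sided p from the t
#' distribution. With zero pooled variance the p-value is 1 for equal means
#' and 0 (flagged degenerate) otherwise.
#'
#' @param group1,group2 numeric vectors, each `n >= 2`.
#' @param welch use Welch's correction instead of the pooled variance.
#' @return one-row tibble: `statistic`, `df`, `p`, `method`, `degenerate`.
#' @export
unpaired_t_test <- function(group1, group2, welch = FALSE) {
  check_finite(group1, "group1"); check_finite(group2, "group2")
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) abort2("each group needs n >= 2",
                                 "acidhesion_bad_arg")
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (v1 == 0 && v2 == 0) {
    p <- if (m1 == m2) 1 else 0
    return(tibble(statistic = if (m1 == m2) 0 else Inf,
                  df = NA_real_, p = p,
                  method = if (welch) "welch_t" else "pooled_t",
                  degenerate = TRUE))
  }
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tstat <- (m1 - m2) / se
  tibble(statistic = tstat, df = df,
         p = 2 * stats::pt(-abs(tstat), df),
         method = if (welch) "welch_t" else "pooled_t",
         degenerate = FALSE)
}

#' One-way ANOVA with Bonferroni post-test
#'
#' One-way ANOVA F across `>= 3` groups, followed by all-pairs t-tests that
#' use the pooled within-group mean square as the error term (the classical
#' "Bonferroni post-test" of biology stats packages), with adjusted
#' `p = min(1, m * raw p)` for `m` comparisons.
#'
#' @param groups named list of numeric vectors, each `n >= 2`.
#' @return list with `anova` (one-row tibble: `F`, `df1`, `df2`, `p`) and
#'   `pairs` (tibble per comparison: `group1`, `group2`, `statistic`, `df`,
#'   `p_raw`, `p_adjusted`).
#' @export
anova_bonferroni <- function(groups) {
  if (length(groups) < 3L) abort2("need >= 3 groups", "acidhesion_bad_arg")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) abort2("every group needs n >= 2", "acidhesion_bad_arg")
  for (g in groups) check_finite(g, "group values")
  k <- length(groups)
  N <- sum(ns)
  means <- unname(vapply(groups, mean, numeric(1)))
  ns <- unname(ns)
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  ms_between <- ss_between / df1
  mse <- ss_within / df2
  fstat <- if (mse > 0) ms_between / mse else if (ss_between == 0) 0 else Inf
  p_f <- if (is.finite(fstat)) stats::pf(fstat, df1, df2, lower.tail = FALSE)
         else 0
  cmb <- utils::combn(k, 2)
  m <- ncol(cmb)
  pairs <- lapply(seq_len(m), function(j) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    se <- sqrt(mse * (1 / ns[i1] + 1 / ns[i2]))
    tstat <- if (se > 0) (means[i1] - means[i2]) / se
             else if (means[i1] == means[i2]) 0 else Inf
    p_raw <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df2) else 0
    tibble(group1 = names(groups)[i1], group2 = names(groups)[i2],
           statistic = tstat, df = df2, p_raw = p_raw,
           p_adjusted = min(1, m * p_raw))
  })
  list(anova = tibble(F = fstat, df1 = df1, df2 = df2, p = p_f),
       pairs = dplyr::bind_rows(pairs))
}
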