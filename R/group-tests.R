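#' Two-sample t test from vectors or summary statistics
#'
#' Welch's unequal-variance t test by default (the Welch-Satterthwaite
#' degrees of freedom); `pooled = TRUE` gives the classical
#' equal-variance test. Accepts either two raw vectors or the summary
#' statistics (mean, sd, n) of each group, so published tables can be
#' re-tested without raw data.
#'
#' @param m1,m2 group means, or raw numeric vectors if `sd1` is `NULL`.
#' @param sd1,sd2 group sample standard deviations.
#' @param n1,n2 group sizes (>= 2).
#' @param pooled use the pooled-variance statistic instead of Welch.
#' @return List with `t`, `df`, `p_value` (two-sided) and `degenerate`
#'   (both sds zero).
#' @examples
#' welch_t_test(10, 12, sd1 = 1, sd2 = 1, n1 = 6, n2 = 6)
#' @export
welch_t_test <- function(m1, m2, sd1 = NULL, sd2 = NULL,
                         n1 = NULL, n2 = NULL, pooled = FALSE) {
  if (is.null(sd1)) {
    x <- as.numeric(m1); y <- as.numeric(m2)
    m1 <- mean(x); m2 <- mean(y)
    sd1 <- stats::sd(x); sd2 <- stats::sd(y)
    n1 <- length(x); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (m1 == m2) {
      return(list(t = 0, df = n1 + n2 - 2, p_value = 1, degenerate = TRUE))
    }
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p_value = 0,
                degenerate = TRUE))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

#' Two-sided F test for equality of variances
#'
#' `F = sd1^2 / sd2^2` on `(n1 - 1, n2 - 1)` degrees of freedom, with
#' the two-sided p-value `2 * min(lower tail, upper tail)`, capped at 1.
#'
#' @param sd1,sd2 sample standard deviations (`sd2 > 0`).
#' @param n1,n2 group sizes (>= 2).
#' @return List with `F`, `df1`, `df2`, `p_value` and `infinite_F`
#'   (TRUE when the denominator variance is zero).
#' @examples
#' f_variance_test(0.471, 0.175, n1 = 6, n2 = 6)$p_value  # ~0.049
#' @export
f_variance_test <- function(sd1, sd2, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd2 <= 0) {
    if (sd1 > 0) {
      return(list(F = Inf, df1 = n1 - 1, df2 = n2 - 1, p_value = 0,
                  infinite_F = TRUE))
    }
    stop("both variances zero: F undefined")
  }
  F <- (sd1 / sd2)^2
  lo <- stats::pf(F, n1 - 1, n2 - 1)
  p <- min(1, 2 * min(lo, 1 - lo))
  list(F = F, df1 = n1 - 1, df2 = n2 - 1, p_value = p, infinite_F = FALSE)
}

#' Tukey honestly-significant-difference comparisons between tools
#'
#' One-way ANOVA with tool as the factor, run separately per dimension,
#' followed by Tukey HSD (studentized-range) adjusted pairwise
#' p-values. Thin wrapper over [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param table a [measurement_table()], or a numeric vector `values`
#'   with a parallel factor `groups`.
#' @param values,groups used when `table` is not given.
#' @return For a table: named list (per dimension) of data frames with
#'   columns `comparison`, `diff`, `lwr`, `upr`, `p_adj`. For vectors: a
#'   single such data frame.
#' @export
tukey_hsd <- function(table = NULL, values = NULL, groups = NULL) {
  if (!is.null(table)) {
    stopifnot(inherits(table, "measurement_table"))
    dims <- levels(droplevels(table$dimension))
    res <- lapply(dims, function(d) {
      sel <- table$dimension == d
      tukey_hsd(values = table$value_mm[sel],
                groups = droplevels(table$tool_id[sel]))
    })
    names(res) <- dims
    return(res)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  cnt <- table(groups)
  if (any(cnt < 2)) {
    stop("singleton group: ", names(cnt)[which(cnt < 2)[1]])
  }
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  tk <- stats::TukeyHSD(fit)$groups
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}
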