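#' Technical error of measurement (TEM)
#'
#' The TEM is the pooled within-subject, between-observer standard
#' deviation of repeated measurements:
#' \deqn{TEM = \sqrt{\frac{\sum_1^N\left(\sum_1^K M^2 -
#'   (\sum_1^K M)^2 / K\right)}{N(K-1)}}}
#' where `M` are the measurements, `N` the number of subjects and `K`
#' the number of observers. Algebraically this equals the square root of
#' the mean across subjects of the within-subject sample variance, which
#' is how [tem_from_sds()] recovers the TEM from published cell
#' standard deviations.
#'
#' When given a `measurement_table`, subjects are the (tool, dimension)
#' cells pooled across length/width/thickness so that a single global
#' TEM in mm is reported; per-dimension TEMs are also returned because
#' pooling mixes measurement magnitudes.
#'
#' @param x a numeric matrix (rows = subjects, columns = observers) or a
#'   [measurement_table()].
#' @return An object of class `tem_result`: list with `tem`,
#'   `percent_tem`, `grand_mean`, `n_subjects`, `n_observers` and, for
#'   tables, `per_dimension`.
#' @examples
#' m <- rbind(c(10, 12), c(20, 22))
#' compute_tem(m)$tem  # sqrt(2)
#' @export
compute_tem <- function(x) {
  if (inherits(x, "measurement_table")) {
    m <- observer_matrix(x)
    res <- compute_tem(m)
    dims <- levels(droplevels(x$dimension))
    res$per_dimension <- vapply(dims, function(d) {
      compute_tem(observer_matrix(x, dimension = d))$tem
    }, numeric(1))
    return(res)
  }
  m <- as.matrix(x)
  if (!is.numeric(m) || anyNA(m)) stop("complete numeric matrix required")
  K <- ncol(m)
  N <- nrow(m)
  if (K < 2) stop("TEM undefined for fewer than 2 observers")
  # double sum evaluated on row-centred values: algebraically identical
  # (shift invariance) but numerically exact for identical observers
  mc <- m - rowMeans(m)
  ss <- pmax(rowSums(mc^2) - rowSums(mc)^2 / K, 0)
  tem <- sqrt(sum(ss) / (N * (K - 1)))
  gm <- mean(m)
  structure(list(tem = tem,
                 percent_tem = compute_percent_tem(tem, gm),
                 grand_mean = gm, n_subjects = N, n_observers = K),
            class = "tem_result")
}

#' TEM from published cell standard deviations
#'
#' For a balanced design the TEM equals the root mean square of the
#' per-subject between-observer sample standard deviations, so a TEM can
#' be recomputed from a published summary table without the raw data.
#'
#' @param sds numeric vector of within-cell (between-observer) sample
#'   standard deviations, one per subject.
#' @return The TEM in the units of `sds`.
#' @examples
#' tem_from_sds(c(0.2, 0.4, 0.3))
#' @export
tem_from_sds <- function(sds) {
  sds <- as.numeric(sds)
  if (any(!is.finite(sds)) || any(sds < 0)) stop("sds must be finite and >= 0")
  sqrt(mean(sds^2))
}

#' Percentage TEM
#'
#' Expresses the TEM as a percentage of the grand mean of the raw
#' measurements: `100 * tem / grand_mean`. In a balanced design the
#' grand mean of the raw values equals the mean of the cell means, so a
#' published table of cell means suffices.
#'
#' @param tem nonnegative TEM.
#' @param grand_mean positive mean of all raw measurements.
#' @return Percentage (e.g. `0.91` means 0.91%).
#' @export
compute_percent_tem <- function(tem, grand_mean) {
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop("grand_mean must be > 0")
  }
  if (tem < 0) stop("tem must be >= 0")
  100 * tem / grand_mean
}

#' Coefficient of reliability between two observers
#'
#' \deqn{R = \sigma_v^2 / (\sigma_v^2 + \sigma_d^2)}
#' where \eqn{\sigma_v^2} is the sample variance of the pooled raw
#' measurements of the pair and \eqn{\sigma_d^2} the sample variance of
#' the paired differences. R ranges from 0 to 1; 1 indicates that all
#' variance is between specimens rather than between the observers.
#'
#' @param a,b equal-length numeric vectors, paired by subject.
#' @return List of class `reliability_result`: `sigma_v_sq`,
#'   `sigma_d_sq`, `R`, `degenerate` (TRUE when the pooled variance is
#'   zero and R is undefined, reported as NA).
#' @examples
#' reliability_R(c(10, 20, 30), c(11, 19, 33))$R
#' @export
reliability_R <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("pairing error: vectors differ in length")
  if (length(a) < 2) stop("need at least 2 paired values")
  sv <- stats::var(c(a, b))
  sd2 <- stats::var(a - b)
  degenerate <- (sv + sd2) == 0
  structure(list(sigma_v_sq = sv, sigma_d_sq = sd2,
                 R = if (degenerate) NA_real_ else sv / (sv + sd2),
                 degenerate = degenerate),
            class = "reliability_result")
}

#' Pairwise reliability matrix across observers
#'
#' Applies [reliability_R()] to every pair of observer columns,
#' pooling all subjects (rows) into the paired vectors.
#'
#' @param m numeric matrix, rows = subjects, columns = observers, or a
#'   [measurement_table()] (pivoted via [observer_matrix()]).
#' @return Symmetric K x K matrix of R values with unit diagonal.
#' @export
pairwise_reliability <- function(m) {
  if (inherits(m, "measurement_table")) m <- observer_matrix(m)
  K <- ncol(m)
  out <- diag(1, K)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      out[i, j] <- out[j, i] <- reliability_R(m[, i], m[, j])$R
    }
  }
  out
}

#' Intraclass correlation from two-way ANOVA mean squares
#'
#' Single-rater ICC estimates computed from the mean squares of the
#' subjects-by-raters layout: `MSR` between subjects (rows), `MSC`
#' between raters (columns), `MSE` the residual, `MSW` the within-subject
#' mean square. Variants:
#' \describe{
#'   \item{`"two-way-agreement"`}{ICC(A,1): `(MSR - MSE) / (MSR + (K-1) MSE
#'     + K (MSC - MSE) / N)`. Penalizes systematic rater offsets.
#'     Default, matching an absolute-agreement reading of a two-way
#'     mixed-effects design with observers fixed.}
#'   \item{`"two-way-consistency"`}{ICC(C,1): `(MSR - MSE) / (MSR +
#'     (K-1) MSE)`. Ignores rater offsets.}
#'   \item{`"one-way"`}{ICC(1): `(MSR - MSW) / (MSR + (K-1) MSW)`.}
#' }
#' The F statistic and p-value test `MSR / MSE` (or `MSR / MSW` for the
#' one-way variant) against the hypothesis of no subject effect.
#' Confidence bounds follow the standard exact (consistency, one-way)
#' and Satterthwaite (agreement) constructions.
#'
#' @param m complete numeric matrix, N subjects x K raters, N, K >= 2.
#' @param variant one of `"two-way-agreement"`, `"two-way-consistency"`,
#'   `"one-way"`.
#' @param conf_level confidence level for the bounds.
#' @return List of class `icc_result`: `estimate`, `variant`, `F`,
#'   `df1`, `df2`, `p_value`, `lower`, `upper`.
#' @examples
#' icc_estimate(cbind(1:6, 1:6 + 0.1))$estimate
#' @export
icc_estimate <- function(m,
                         variant = c("two-way-agreement",
                                     "two-way-consistency", "one-way"),
                         conf_level = 0.95) {
  variant <- match.arg(variant)
  m <- as.matrix(m)
  if (anyNA(m)) stop("balance error: ICC requires a complete matrix")
  N <- nrow(m); K <- ncol(m)
  if (N < 2 || K < 2) stop("need at least 2 subjects and 2 raters")

  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  SSR <- K * sum((rm_ - grand)^2)
  SSC <- N * sum((cm_ - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  SSW <- SST - SSR
  MSR <- SSR / (N - 1)
  MSC <- SSC / (K - 1)
  MSE <- SSE / ((N - 1) * (K - 1))
  MSW <- SSW / (N * (K - 1))

  alpha <- 1 - conf_level
  if (variant == "one-way") {
    est <- safe_ratio(MSR - MSW, MSR + (K - 1) * MSW)
    Fst <- safe_ratio(MSR, MSW)
    df1 <- N - 1; df2 <- N * (K - 1)
    FL <- Fst / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fst * stats::qf(1 - alpha / 2, df2, df1)
    lower <- (FL - 1) / (FL + K - 1)
    upper <- (FU - 1) / (FU + K - 1)
  } else {
    Fst <- safe_ratio(MSR, MSE)
    df1 <- N - 1; df2 <- (N - 1) * (K - 1)
    if (variant == "two-way-consistency") {
      est <- safe_ratio(MSR - MSE, MSR + (K - 1) * MSE)
      FL <- Fst / stats::qf(1 - alpha / 2, df1, df2)
      FU <- Fst * stats::qf(1 - alpha / 2, df2, df1)
      lower <- (FL - 1) / (FL + K - 1)
      upper <- (FU - 1) / (FU + K - 1)
    } else {
      est <- safe_ratio(MSR - MSE,
                        MSR + (K - 1) * MSE + K * (MSC - MSE) / N)
      ci <- icc_agreement_ci(est, MSR, MSC, MSE, N, K, alpha)
      lower <- ci[1]; upper <- ci[2]
    }
  }
  p <- if (is.finite(Fst)) stats::pf(Fst, df1, df2, lower.tail = FALSE) else 0
  structure(list(estimate = est, variant = variant,
                 F = Fst, df1 = df1, df2 = df2, p_value = p,
                 lower = max(-1, min(lower, est)),
                 upper = min(1, max(upper, est)),
                 MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW),
            class = "icc_result")
}

# Satterthwaite CI for the single-rater agreement ICC (McGraw & Wong).
icc_agreement_ci <- function(est, MSR, MSC, MSE, N, K, alpha) {
  if (!is.finite(est)) return(c(NA_real_, NA_real_))
  a <- K * est / (N * (1 - est))
  b <- 1 + K * est * (N - 1) / (N * (1 - est))
  if (!is.finite(a) || !is.finite(b)) return(c(est, est))
  v_num <- (a * MSC + b * MSE)^2
  v_den <- (a * MSC)^2 / (K - 1) + (b * MSE)^2 / ((N - 1) * (K - 1))
  v <- if (v_den > 0) v_num / v_den else Inf
  # Satterthwaite df can be enormous near perfect agreement; qf then
  # warns about its own tail accuracy, which is immaterial here
  FL <- suppressWarnings(stats::qf(1 - alpha / 2, N - 1, v))
  FU <- suppressWarnings(stats::qf(1 - alpha / 2, v, N - 1))
  lower <- N * (MSR - FL * MSE) /
    (FL * (K * MSC + (K * N - K - N) * MSE) + N * MSR)
  upper <- N * (FU * MSR - MSE) /
    (K * MSC + (K * N - K - N) * MSE + N * FU * MSR)
  c(lower, upper)
}

safe_ratio <- function(num, den) {
  if (den == 0) {
    if (num == 0) 1 else Inf
  } else {
    num / den
  }
}
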