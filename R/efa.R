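#' Normalize an outline for shape comparison
#'
#' Standardizes an outline geometrically before elliptic Fourier
#' analysis: the centroid is moved to the origin, the configuration is
#' divided by its centroid size (RMS radius, see [centroid_size()]),
#' and the points are rotated so the dominant eigenvector of their 2x2
#' coordinate covariance — the long axis — lies along x. The 180-degree
#' ambiguity of the axis is resolved deterministically by requiring the
#' third central moment of x to be nonnegative (falling back to the
#' sign of the y third moment when |moment| < 1e-9), and the start
#' point is moved to the vertex with maximal x (ties broken by larger
#' y) so that independently digitized copies of one shape align.
#'
#' @param o an [outline()], >= 3 non-collinear points.
#' @return A normalized [outline()] (dimensionless units) with
#'   attribute `normalized = TRUE`.
#' @export
normalize_outline <- function(o) {
  xy <- as.matrix(o)
  if (nrow(xy) < 3) stop("need >= 3 points")
  xy <- sweep(xy, 2, colMeans(xy))
  cs <- sqrt(sum(xy^2) / nrow(xy))
  if (cs == 0) stop("degenerate outline: zero centroid size")
  xy <- xy / cs
  cv <- stats::cov(xy)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] < 1e-12 * ev$values[1]) {
    stop("degenerate scatter: points are (nearly) collinear")
  }
  if (ev$values[1] - ev$values[2] < 1e-12 * ev$values[1]) {
    # isotropic scatter (e.g. a circle): long axis undefined, keep frame
    rot <- diag(2)
  } else {
    v <- ev$vectors[, 1]
    rot <- rbind(c(v[1], v[2]), c(-v[2], v[1]))  # rotate v onto x-axis
  }
  xy <- xy %*% t(rot)
  m3x <- mean(xy[, 1]^3)
  flip <- if (abs(m3x) >= 1e-9) m3x < 0 else mean(xy[, 2]^3) < 0
  if (flip) xy <- -xy
  # orientation flips under point reflection; restore ccw, keep start
  if (signed_area(xy) < 0) xy <- xy[c(1, nrow(xy):2), , drop = FALSE]
  start <- order(-xy[, 1], -xy[, 2])[1]
  if (start > 1) xy <- xy[c(start:nrow(xy), 1:(start - 1)), , drop = FALSE]
  out <- outline(xy, units = "shape", tool_id = attr(o, "tool_id"),
                 observer_id = attr(o, "observer_id"),
                 image_id = attr(o, "image_id"))
  attr(out, "normalized") <- TRUE
  out
}

#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes the classical chain-coded / arc-length-parametrized
#' elliptic Fourier coefficients of a closed polygon: with the outline
#' traversed at uniform speed over total perimeter T, the coordinates
#' are expanded as
#' \deqn{x(t) = a_0 + \sum_n a_n \cos(2\pi n t/T) + b_n \sin(2\pi n t/T)}
#' and likewise y(t) with coefficients \eqn{c_n, d_n}. Each harmonic
#' contributes the quadruple (a_n, b_n, c_n, d_n); harmonic 1 is the
#' best-fitting ellipse.
#'
#' @param o an [outline()] (closed polygon).
#' @param h number of harmonics, `1 <= h <= n_points / 2`.
#' @return Object of class `efa_coefficients`: list with matrices
#'   `an`, `bn`, `cn`, `dn` (length-h vectors), centre terms `a0`,
#'   `c0`, and metadata copied from the outline.
#' @export
efa_forward <- function(o, h) {
  xy <- as.matrix(o)
  n <- nrow(xy)
  if (h < 1) stop("h must be >= 1")
  if (h > n / 2) stop("h must not exceed n_points / 2")
  nxt <- c(2:n, 1)
  dx <- xy[nxt, 1] - xy[, 1]
  dy <- xy[nxt, 2] - xy[, 2]
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) stop("outline has zero-length edges")
  t1 <- cumsum(dt)          # arc length at end of edge i
  t0 <- c(0, t1[-n])        # arc length at start of edge i
  T <- t1[n]
  w <- 2 * pi / T

  an <- bn <- cn <- dn <- numeric(h)
  for (k in seq_len(h)) {
    cos1 <- cos(k * w * t1); cos0 <- cos(k * w * t0)
    sin1 <- sin(k * w * t1); sin0 <- sin(k * w * t0)
    cf <- T / (2 * pi^2 * k^2)
    an[k] <- cf * sum(dx / dt * (cos1 - cos0))
    bn[k] <- cf * sum(dx / dt * (sin1 - sin0))
    cn[k] <- cf * sum(dy / dt * (cos1 - cos0))
    dn[k] <- cf * sum(dy / dt * (sin1 - sin0))
  }
  # dc terms: mean position of the uniform-speed traversal; on edge i the
  # mean x-offset from the start vertex is cumsum(dx) - dx/2
  a0 <- xy[1, 1] + sum(dt * (cumsum(dx) - dx / 2)) / T
  c0 <- xy[1, 2] + sum(dt * (cumsum(dy) - dy / 2)) / T
  structure(list(an = an, bn = bn, cn = cn, dn = dn, a0 = a0, c0 = c0,
                 h = h, perimeter = T,
                 tool_id = attr(o, "tool_id"),
                 observer_id = attr(o, "observer_id"),
                 image_id = attr(o, "image_id")),
            class = "efa_coefficients")
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values over one traversal.
#'
#' @param coeffs an `efa_coefficients` object (see [efa_forward()]).
#' @param n_points number of points to evaluate (>= 3).
#' @param h number of harmonics to use (default: all available).
#' @return An [outline()].
#' @export
efa_inverse <- function(coeffs, n_points = 300, h = coeffs$h) {
  stopifnot(inherits(coeffs, "efa_coefficients"))
  if (n_points < 3) stop("n_points must be >= 3")
  if (h > coeffs$h) stop("requested more harmonics than available")
  t <- 2 * pi * (seq_len(n_points) - 1) / n_points
  x <- rep(coeffs$a0, n_points)
  y <- rep(coeffs$c0, n_points)
  for (k in seq_len(h)) {
    ck <- cos(k * t); sk <- sin(k * t)
    x <- x + coeffs$an[k] * ck + coeffs$bn[k] * sk
    y <- y + coeffs$cn[k] * ck + coeffs$dn[k] * sk
  }
  outline(cbind(x, y), units = "shape", tool_id = coeffs$tool_id,
          observer_id = coeffs$observer_id, image_id = coeffs$image_id)
}

#' Harmonic power profile
#'
#' Per-harmonic power \eqn{P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2}
#' and its cumulative fraction, used to decide how many harmonics carry
#' essentially all shape information.
#'
#' @param coeffs an `efa_coefficients` object.
#' @param include_first include harmonic 1 in the totals (default TRUE).
#' @return Data frame with columns `harmonic`, `power`,
#'   `cumulative_fraction`.
#' @export
harmonic_power <- function(coeffs, include_first = TRUE) {
  stopifnot(inherits(coeffs, "efa_coefficients"))
  p <- (coeffs$an^2 + coeffs$bn^2 + coeffs$cn^2 + coeffs$dn^2) / 2
  keep <- if (include_first) seq_along(p) else -1L
  tot <- sum(p[keep])
  if (tot == 0) stop("zero total harmonic power")
  cf <- cumsum(p) / tot
  if (!include_first) cf <- cf - cf[1]
  data.frame(harmonic = seq_along(p), power = p, cumulative_fraction = cf)
}

#' Select the number of harmonics by cumulative power
#'
#' Computes the harmonic power profile up to `h_max` and returns the
#' smallest harmonic count whose cumulative power fraction reaches the
#' threshold (0.99 by default, the conventional cut-off for outline
#' studies).
#'
#' @param o an [outline()].
#' @param threshold required cumulative power fraction, in (0, 1].
#' @param h_max maximum harmonics examined (must be <= n_points / 2).
#' @param include_first include harmonic 1 in the power totals.
#' @return List with `profile` (see [harmonic_power()]) and
#'   `h_selected`.
#' @export
harmonic_power_select <- function(o, threshold = 0.99, h_max = 32,
                                  include_first = TRUE) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  coeffs <- efa_forward(o, h_max)
  prof <- harmonic_power(coeffs, include_first = include_first)
  hit <- which(prof$cumulative_fraction >= threshold - 1e-12)
  h_sel <- if (length(hit) == 0) h_max else hit[1]
  list(profile = prof, h_selected = h_sel)
}

#' Flatten EFA coefficient sets into a matrix
#'
#' One row per outline, columns `a1..ah, b1..bh, c1..ch, d1..dh`, with
#' tool and observer labels carried alongside — the input expected by
#' [pca_fit()].
#'
#' @param coeff_list list of `efa_coefficients`, all with the same `h`.
#' @return List with `x` (numeric matrix), `tool_id`, `observer_id`
#'   (factors).
#' @export
coefficient_matrix <- function(coeff_list) {
  hs <- vapply(coeff_list, function(cc) cc$h, numeric(1))
  if (length(unique(hs)) != 1) stop("all coefficient sets must share h")
  h <- hs[1]
  x <- t(vapply(coeff_list, function(cc) c(cc$an, cc$bn, cc$cn, cc$dn),
                numeric(4 * h)))
  colnames(x) <- c(paste0("a", 1:h), paste0("b", 1:h),
                   paste0("c", 1:h), paste0("d", 1:h))
  list(x = x,
       tool_id = factor(vapply(coeff_list, function(cc)
         as.character(cc$tool_id), character(1))),
       observer_id = factor(vapply(coeff_list, function(cc)
         as.character(cc$observer_id), character(1))))
}
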