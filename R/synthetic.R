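#' Observer effect parameters for the synthetic generator
#'
#' Bundles the error structure of one simulated multi-observer study.
#' Photographic distortion is applied once per observer (each observer
#' has one camera and set-up): a multiplicative scale-calibration error
#' (log-normal, spread `scale_sd`) and a horizontal shear (the parallax
#' surrogate, drawn Normal with sd `shear_sd`). Digitization noise is
#' per outline: smoothed radial displacement with sd a fraction
#' `radial_noise_sd` of the RMS radius, smoothed over `smooth_window`
#' neighbouring points. Calliper error is a per-observer,
#' per-dimension bias (sd `bias_sd`, mm) plus an independent residual
#' (sd `resid_sd`, mm), with values rounded to `quantum` (0.1 mm, the
#' resolution of a digital calliper).
#'
#' @param scale_sd log-scale sd of the multiplicative scale error.
#' @param shear_sd sd of the observer-level shear coefficient.
#' @param radial_noise_sd digitization noise, fraction of RMS radius.
#' @param smooth_window odd integer moving-average window (points).
#' @param bias_sd per-observer measurement bias sd, mm.
#' @param resid_sd residual measurement noise sd, mm.
#' @param quantum rounding quantum, mm.
#' @return List of class `observer_effect`.
#' @export
observer_effect <- function(scale_sd = 0.01, shear_sd = 0.02,
                            radial_noise_sd = 0.005, smooth_window = 5,
                            bias_sd = 0.2, resid_sd = 0.2, quantum = 0.1) {
  vals <- c(scale_sd, shear_sd, radial_noise_sd, bias_sd, resid_sd)
  if (any(vals < 0)) stop("all spreads must be >= 0")
  if (quantum <= 0) stop("quantum must be > 0")
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("smooth_window must be a positive odd integer")
  }
  structure(list(scale_sd = scale_sd, shear_sd = shear_sd,
                 radial_noise_sd = radial_noise_sd,
                 smooth_window = smooth_window, bias_sd = bias_sd,
                 resid_sd = resid_sd, quantum = quantum),
            class = "observer_effect")
}

#' Generate tool archetypes
#'
#' Creates `n_tools` distinct elongated, point-like reference shapes.
#' Each is built as a star-shaped radial perturbation of an ellipse
#' (guaranteeing a simple closed curve), scaled to a realistic
#' projectile-point size (length 55-90 mm, width 0.35-0.65 of length,
#' thickness 6-15 mm), then encoded as elliptic Fourier coefficients.
#' Deterministic for a fixed seed.
#'
#' @param n_tools number of archetypes (>= 1).
#' @param seed RNG seed.
#' @param h harmonics stored per archetype (>= 4).
#' @return List of `archetype` objects: each has `tool_id`, `coeffs`
#'   (an `efa_coefficients` in cm), `outline` (the base outline, cm)
#'   and `true_length_mm`, `true_width_mm`, `true_thickness_mm`.
#' @export
make_archetypes <- function(n_tools = 6, seed = 1, h = 8) {
  if (n_tools < 1) stop("n_tools must be >= 1")
  if (h < 4) stop("h must be >= 4")
  set.seed(seed)
  lapply(seq_len(n_tools), function(t) {
    len_mm <- stats::runif(1, 55, 90)
    wid_mm <- len_mm * stats::runif(1, 0.35, 0.65)
    thick_mm <- stats::runif(1, 6, 15)
    theta <- 2 * pi * (0:359) / 360
    r <- rep(1, 360)
    # radial detail rich enough that several harmonics are needed to
    # reach 99% power, as for real knapped pieces with worked edges
    for (k in 2:8) {
      r <- r + stats::rnorm(1, 0, 0.25 / k) * cos(k * theta) +
        stats::rnorm(1, 0, 0.25 / k) * sin(k * theta)
    }
    # pointedness: pinch the outline towards the +x tip
    r <- r * (1 - 0.3 * (1 + cos(theta)) / 2 * abs(sin(theta)))
    r <- pmax(r, 0.25)
    xy_mm <- cbind(len_mm / 2 * r * cos(theta), wid_mm / 2 * r * sin(theta))
    o <- resample_equidistant(outline(xy_mm / 10, units = "cm",
                                      tool_id = t), 360)
    structure(list(tool_id = t,
                   coeffs = efa_forward(o, h),
                   outline = o,
                   true_length_mm = diff(range(xy_mm[, 1])),
                   true_width_mm = diff(range(xy_mm[, 2])),
                   true_thickness_mm = thick_mm),
              class = "archetype")
  })
}

#' Simulate multi-observer outline captures
#'
#' For each observer draws one scale factor (log-normal) and one shear
#' coefficient, applies them to every archetype's base outline, and
#' adds smoothed radial digitization noise per outline — emulating
#' independent photography and digitization of identical replicas.
#'
#' @param archetypes output of [make_archetypes()].
#' @param n_observers number of observers.
#' @param effect an [observer_effect()].
#' @param seed RNG seed.
#' @param n_points points per simulated outline.
#' @return List of [outline()]s (cm) with tool and observer metadata.
#' @export
simulate_outlines <- function(archetypes, n_observers,
                              effect = observer_effect(), seed = 1,
                              n_points = 360) {
  stopifnot(inherits(effect, "observer_effect"))
  set.seed(seed)
  out <- vector("list", length(archetypes) * n_observers)
  i <- 0
  for (j in seq_len(n_observers)) {
    s_j <- exp(stats::rnorm(1, 0, effect$scale_sd))
    eps_j <- stats::rnorm(1, 0, effect$shear_sd)
    for (a in archetypes) {
      base <- resample_equidistant(a$outline, n_points)
      xy <- as.matrix(base)
      xy <- cbind(s_j * (xy[, 1] + eps_j * xy[, 2]), s_j * xy[, 2])
      if (effect$radial_noise_sd > 0) {
        ctr <- colMeans(xy)
        cxy <- sweep(xy, 2, ctr)
        rr <- sqrt(rowSums(cxy^2))
        rms <- sqrt(mean(rr^2))
        noise <- circular_smooth(
          stats::rnorm(n_points, 0, effect$radial_noise_sd * rms),
          effect$smooth_window)
        xy <- sweep(cxy * (1 + noise / pmax(rr, 1e-12)), 2, ctr, "+")
      }
      i <- i + 1
      out[[i]] <- outline(xy, units = "cm", tool_id = a$tool_id,
                          observer_id = j,
                          image_id = sprintf("t%s_o%d", a$tool_id, j))
    }
  }
  out
}

# circular moving average with an odd window
circular_smooth <- function(v, window) {
  if (window <= 1) return(v)
  half <- (window - 1) / 2
  n <- length(v)
  vv <- c(v[(n - half + 1):n], v, v[1:half])
  as.numeric(stats::filter(vv, rep(1 / window, window)))[half + seq_len(n)]
}

#' Rasterize an outline to a silhouette image
#'
#' Fills the outline polygon as dark foreground (intensity 0) on a
#' light ground (intensity 1), with the outline centroid placed at the
#' canvas centre. Pixel (row r, column c) has maths coordinates
#' x = c, y = nrow - 1 - r (0-based, y-up), the same frame
#' [binarize_and_extract()] reports, so render-extract round trips are
#' direct.
#'
#' @param o an [outline()] in cm.
#' @param px_per_cm pixels per centimetre.
#' @param canvas integer `c(rows, cols)` canvas size in pixels.
#' @return A [silhouette_image()]; attribute `origin_px` gives the
#'   offset such that `px = cm * px_per_cm + origin_px`.
#' @export
render_image <- function(o, px_per_cm = 100, canvas = c(512, 512)) {
  xy_px <- as.matrix(o) * px_per_cm
  ctr <- colMeans(xy_px)
  offset <- c((canvas[2] - 1) / 2, (canvas[1] - 1) / 2) - ctr
  xy_px <- sweep(xy_px, 2, offset, "+")
  if (any(xy_px[, 1] < 1) || any(xy_px[, 1] > canvas[2] - 2) ||
      any(xy_px[, 2] < 1) || any(xy_px[, 2] > canvas[1] - 2)) {
    stop("outline exceeds canvas at this scale")
  }
  grid <- cbind(rep(0:(canvas[2] - 1), each = canvas[1]),
                rep((canvas[1] - 1):0, times = canvas[2]))
  inside <- mgcv::in.out(rbind(xy_px, xy_px[1, ]), grid)
  # grid runs down each column (rows top to bottom), then across columns
  m <- matrix(ifelse(inside, 0, 1), canvas[1], canvas[2])
  img <- silhouette_image(m, px_per_cm, image_id = attr(o, "image_id"),
                          tool_id = attr(o, "tool_id"),
                          observer_id = attr(o, "observer_id"))
  attr(img, "origin_px") <- offset
  img
}

#' Simulate a multi-observer measurement table
#'
#' Each observer reports, for every archetype and dimension,
#' `true value + bias + noise` rounded to the calliper quantum; the
#' bias is drawn once per (observer, dimension), emulating systematic
#' differences in landmark interpretation and instrument, the noise
#' independently per record.
#'
#' @param archetypes output of [make_archetypes()].
#' @param n_observers number of observers.
#' @param effect an [observer_effect()].
#' @param seed RNG seed.
#' @param n_replicates replicates per (tool, observer) (default 1).
#' @return A balanced [measurement_table()].
#' @export
simulate_measurements <- function(archetypes, n_observers,
                                  effect = observer_effect(), seed = 1,
                                  n_replicates = 1) {
  stopifnot(inherits(effect, "observer_effect"))
  set.seed(seed)
  dims <- c("length", "width", "thickness")
  rows <- list()
  for (j in seq_len(n_observers)) {
    bias <- stats::rnorm(3, 0, effect$bias_sd)
    names(bias) <- dims
    for (a in archetypes) {
      truth <- c(length = a$true_length_mm, width = a$true_width_mm,
                 thickness = a$true_thickness_mm)
      for (r in seq_len(n_replicates)) {
        val <- truth + bias + stats::rnorm(3, 0, effect$resid_sd)
        val <- round(val / effect$quantum) * effect$quantum
        rows[[length(rows) + 1]] <- data.frame(
          tool_id = a$tool_id, observer_id = j, replicate_id = r,
          dimension = dims, value_mm = pmax(val, effect$quantum))
      }
    }
  }
  df <- do.call(rbind, rows)
  measurement_table(df$tool_id, df$observer_id, df$replicate_id,
                    df$dimension, df$value_mm)
}
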