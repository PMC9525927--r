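# shared shape fixtures, built in code

circle_outline <- function(r = 1, n = 512, units = "cm", ...) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  outline(cbind(r * cos(th), r * sin(th)), units = units, ...)
}

ellipse_outline <- function(a = 1.2, b = 1, n = 512, angle = 0, units = "cm") {
  th <- 2 * pi * (seq_len(n) - 1) / n
  xy <- cbind(a * cos(th), b * sin(th))
  rot <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  outline(xy %*% t(rot), units = units)
}

# smooth non-elliptical blob, star-shaped so always simple
blob_outline <- function(n = 512, seed = 3) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1
  for (k in 2:6) {
    r <- r + rnorm(1, 0, 0.2 / k) * cos(k * th) +
      rnorm(1, 0, 0.2 / k) * sin(k * th)
  }
  outline(cbind(1.4 * r * cos(th), r * sin(th)))
}

# balanced random subjects-by-observers matrix
random_obs_matrix <- function(n = 8, k = 4, seed = 1, subject_sd = 2,
                              noise_sd = 0.3) {
  set.seed(seed)
  matrix(rnorm(n * k, 0, noise_sd), n, k) + rnorm(n, 10, subject_sd)
}

# star-shapedness about the centroid implies a simple closed polygon
expect_simple_polygon <- function(o) {
  xy <- sweep(as.matrix(o), 2, colMeans(as.matrix(o)))
  ang <- atan2(xy[, 2], xy[, 1])
  d <- diff(ang)
  d <- d[abs(d) < pi]  # ignore the single wrap-around
  expect_true(all(d > 0) || all(d < 0))
}
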