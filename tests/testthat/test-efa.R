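test_that("normalization centres, scales and aligns the long axis", {
  o <- ellipse_outline(a = 2, b = 1, n = 360, angle = pi / 6)
  no <- normalize_outline(o)
  xy <- as.matrix(no)
  expect_lt(max(abs(colMeans(xy))), 1e-9)
  expect_equal(centroid_size(no), 1, tolerance = 1e-9)
  # eigenvector oracle: after alignment the covariance is diagonal with
  # the large eigenvalue on x
  cv <- cov(xy)
  expect_lt(abs(atan2(eigen(cv)$vectors[2, 1], eigen(cv)$vectors[1, 1])) %%
              pi, 1e-6)
  expect_gt(cv[1, 1], cv[2, 2])
})

test_that("normalization is idempotent and deterministic about flips", {
  b <- blob_outline(300, seed = 11)
  n1 <- normalize_outline(b)
  n2 <- normalize_outline(n1)
  expect_equal(as.matrix(n2), as.matrix(n1), tolerance = 1e-9)
  # a rotated + translated + scaled copy lands on the same points
  ang <- 1.1
  rot <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  copy <- outline(sweep(as.matrix(b) %*% t(rot) * 3.7, 2, c(5, -2), "+"))
  expect_equal(as.matrix(normalize_outline(copy)), as.matrix(n1),
               tolerance = 1e-6)
})

test_that("degenerate scatter is rejected", {
  expect_error(normalize_outline(outline(rbind(c(0, 0), c(1, 1e-14),
                                               c(2, 0)))),
               "degenerate|collinear")
})

test_that("a circle is a pure first harmonic", {
  r <- 3
  cf <- efa_forward(circle_outline(r, 512), 8)
  expect_lt(abs(abs(cf$an[1]) - r), 1e-3 * r)
  expect_lt(abs(abs(cf$dn[1]) - r), 1e-3 * r)
  expect_lt(abs(cf$bn[1]), 1e-3 * r)
  expect_lt(abs(cf$cn[1]), 1e-3 * r)
  pw <- harmonic_power(cf)
  expect_lt(sum(pw$power[-1]) / sum(pw$power), 1e-6)
  expect_equal(harmonic_power_select(circle_outline(r, 512))$h_selected, 1)
})

test_that("an ellipse reaches 99% power at the first harmonic", {
  sel <- harmonic_power_select(ellipse_outline(1.2, 1.0, 512), 0.99, 16)
  expect_equal(sel$h_selected, 1)
  expect_gte(sel$profile$cumulative_fraction[1], 0.99)
})

test_that("harmonic power profiles are monotone and normalized", {
  prof <- harmonic_power(efa_forward(blob_outline(512), 20))
  expect_true(all(diff(prof$cumulative_fraction) >= -1e-15))
  expect_equal(prof$cumulative_fraction[20], 1, tolerance = 1e-12)
  sel <- harmonic_power_select(blob_outline(512), threshold = 1, h_max = 20)
  expect_equal(sel$h_selected, 20)
})

test_that("forward then inverse reconstructs shapes", {
  circ <- circle_outline(2, 512)
  rec <- efa_inverse(efa_forward(circ, 1), 512)
  expect_lt(sqrt(mean((as.matrix(rec) - as.matrix(circ))^2)), 1e-3 * 2)

  b <- resample_equidistant(blob_outline(600, seed = 2), 512)
  cf <- efa_forward(b, 32)
  rmse <- function(h) {
    rec <- as.matrix(efa_inverse(cf, 512, h = h))
    sqrt(mean((rec - as.matrix(b))^2))
  }
  errs <- vapply(c(2, 4, 8, 16, 32), rmse, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 1e-3 * centroid_size(b))
})

test_that("zeroed harmonics collapse the reconstruction onto the centre", {
  cf <- efa_forward(circle_outline(1, 64), 2)
  cf$an[] <- 0; cf$bn[] <- 0; cf$cn[] <- 0; cf$dn[] <- 0
  cf$a0 <- 2.5; cf$c0 <- -1
  # every evaluated point sits at (a0, c0); a constant point set is a
  # degenerate outline, so construction is expected to refuse it
  expect_error(efa_inverse(cf, 10), "degenerate")
})

test_that("EFA is invariant to similarity transforms after normalization", {
  b <- resample_equidistant(blob_outline(400, seed = 4), 256)
  cf1 <- efa_forward(normalize_outline(b), 8)
  ang <- -0.7
  rot <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  moved <- outline(sweep(as.matrix(b) %*% t(rot) * 0.42, 2, c(-3, 8), "+"))
  cf2 <- efa_forward(normalize_outline(moved), 8)
  expect_equal(c(cf1$an, cf1$bn, cf1$cn, cf1$dn),
               c(cf2$an, cf2$bn, cf2$cn, cf2$dn), tolerance = 1e-6)
})

test_that("harmonic limits are enforced", {
  expect_error(efa_forward(circle_outline(1, 16), 9), "exceed")
  expect_error(harmonic_power_select(circle_outline(1, 16), h_max = 20),
               "exceed")
  expect_error(efa_forward(circle_outline(1, 64), 0), ">= 1")
})
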