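test_that("Welch t from summaries matches the distribution oracle", {
  w <- welch_t_test(10, 12, sd1 = 1, sd2 = 1, n1 = 6, n2 = 6)
  expect_equal(w$t, -2 / sqrt(1 / 3), tolerance = 1e-10)
  expect_equal(w$df, 10, tolerance = 1e-10)
  expect_equal(w$p_value, 2 * pt(-abs(w$t), 10), tolerance = 1e-10)

  # identical summaries
  expect_equal(welch_t_test(5, 5, 1, 1, 4, 4)$t, 0)
  expect_equal(welch_t_test(5, 5, 1, 1, 4, 4)$p_value, 1)

  # antisymmetry under group swap
  a <- welch_t_test(10.3, 11.1, 0.7, 1.4, 6, 8)
  b <- welch_t_test(11.1, 10.3, 1.4, 0.7, 8, 6)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  # degenerate: both sds zero
  d <- welch_t_test(3, 3, 0, 0, 5, 5)
  expect_true(d$degenerate); expect_equal(d$p_value, 1)
})

test_that("Welch t on raw vectors agrees with t.test", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(7, 10, 1); y <- rnorm(9, 11, 2)
    ours <- welch_t_test(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-sided F test matches var.test and handles edge cases", {
  eq <- f_variance_test(0.5, 0.5, 6, 6)
  expect_equal(eq$F, 1); expect_equal(eq$p_value, 1)

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(6, 0, 1); y <- rnorm(8, 0, 2)
    ours <- f_variance_test(sd(x), sd(y), 6, 8)
    ref <- var.test(x, y)
    expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }

  inf <- f_variance_test(0.3, 0, 6, 6)
  expect_true(inf$infinite_F); expect_equal(inf$p_value, 0)
  expect_error(f_variance_test(0, 0, 6, 6), "undefined")
})

test_that("published summary sds reproduce the printed F-test p-values", {
  expect_equal(round(f_variance_test(0.471, 0.175, 6, 6)$p_value, 3), 0.049)
  expect_equal(round(f_variance_test(0.415, 0.117, 6, 6)$p_value, 3), 0.015)
})

test_that("Tukey HSD separates distant groups and not identical ones", {
  g <- factor(rep(c("a", "b", "c"), each = 6))
  same <- rep(c(1, 2, 3, 4, 5, 6), 3)
  tk <- tukey_hsd(values = same, groups = g)
  expect_true(all(tk$p_adj > 0.999))

  set.seed(1)
  far <- rep(c(0, 100, 200), each = 6) + rnorm(18, 0, 0.1)
  tk2 <- tukey_hsd(values = far, groups = g)
  expect_true(all(tk2$p_adj < 1e-6))

  expect_error(tukey_hsd(values = c(1, 2, 3), groups = factor(c("a", "a", "b"))),
               "singleton")
})

test_that("Tukey HSD agrees with a permutation oracle on a small case", {
  set.seed(7)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  y <- c(rnorm(4, 0), rnorm(4, 1.5), rnorm(4, 1.6))
  tk <- tukey_hsd(values = y, groups = g)

  # permutation oracle on the max studentized-range statistic: the
  # family-wise p for the largest pairwise gap
  qstat <- function(vals) {
    mns <- tapply(vals, g, mean)
    mse <- sum(tapply(vals, g, function(v) sum((v - mean(v))^2))) / (12 - 3)
    (max(mns) - min(mns)) / sqrt(mse / 4)
  }
  obs <- qstat(y)
  set.seed(8)
  perm <- replicate(4000, qstat(sample(y)))
  p_perm <- mean(perm >= obs)
  widest <- which.max(abs(tk$diff))
  expect_equal(tk$p_adj[widest], p_perm, tolerance = 0.03)
})

test_that("Tukey HSD over a measurement table runs per dimension", {
  set.seed(2)
  g <- expand.grid(tool = 1:3, obs = 1:4)
  vals_l <- 20 + 5 * g$tool + rnorm(12, 0, 0.2)
  vals_w <- 10 + rnorm(12, 0, 0.2)  # no tool effect on width
  mt <- measurement_table(rep(g$tool, 2), rep(g$obs, 2), 1,
                          rep(c("length", "width"), each = 12),
                          c(vals_l, vals_w))
  res <- tukey_hsd(mt)
  expect_named(res, c("length", "width"))
  expect_true(all(res$length$p_adj < 1e-4))
  expect_true(all(res$width$p_adj > 0.05))
})
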