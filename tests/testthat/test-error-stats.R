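test_that("TEM matches the direct double-sum evaluation", {
  # independent oracle: literal double-sum formula
  tem_oracle <- function(m) {
    N <- nrow(m); K <- ncol(m)
    sqrt(sum(apply(m, 1, function(r) sum(r^2) - sum(r)^2 / K)) /
           (N * (K - 1)))
  }
  m <- rbind(c(10, 12), c(20, 22))
  expect_equal(tem_oracle(m), sqrt(2))
  expect_equal(compute_tem(m)$tem, sqrt(2), tolerance = 1e-12)

  # identical observers: zero within-subject variance
  m0 <- cbind(c(5, 9, 13), c(5, 9, 13), c(5, 9, 13))
  expect_equal(compute_tem(m0)$tem, 0)

  expect_error(compute_tem(matrix(1:3, ncol = 1)), "fewer than 2")
  expect_error(compute_tem(matrix(c(1, NA, 3, 4), 2)), "complete")
})

test_that("double-sum TEM equals the pooled within-subject variance identity", {
  for (seed in 1:10) {
    m <- random_obs_matrix(n = 7, k = 5, seed = seed)
    expect_equal(compute_tem(m)$tem,
                 sqrt(mean(apply(m, 1, var))), tolerance = 1e-12)
    expect_equal(compute_tem(m)$tem, tem_from_sds(apply(m, 1, sd)),
                 tolerance = 1e-12)
  }
})

test_that("two-observer TEM reduces to the paired-difference form", {
  for (seed in 1:5) {
    m <- random_obs_matrix(n = 9, k = 2, seed = seed)
    d <- m[, 1] - m[, 2]
    expect_equal(compute_tem(m)$tem, sqrt(sum(d^2) / (2 * nrow(m))),
                 tolerance = 1e-12)
  }
})

test_that("%TEM scales the TEM by the grand mean", {
  expect_equal(compute_percent_tem(0, 12), 0)
  expect_equal(compute_percent_tem(sqrt(2), 16), 100 * sqrt(2) / 16,
               tolerance = 1e-9)
  expect_equal(compute_percent_tem(1.41421, 16), 8.8388, tolerance = 1e-4)
  expect_error(compute_percent_tem(1, 0), "> 0")
  expect_error(compute_percent_tem(1, -3), "> 0")
})

test_that("coefficient of reliability matches hand-computed variances", {
  r <- reliability_R(c(10, 20, 30), c(11, 19, 33))
  expect_equal(r$sigma_v_sq, 89.9, tolerance = 1e-10)
  expect_equal(r$sigma_d_sq, 4, tolerance = 1e-10)
  expect_equal(r$R, 89.9 / 93.9, tolerance = 1e-10)

  # constant offset: zero difference variance
  expect_equal(reliability_R(c(10, 20, 30), c(12, 22, 32))$R, 1)

  # symmetry
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(6, 20, 4); b <- a + rnorm(6, 0, 0.5)
    expect_identical(reliability_R(a, b)$R, reliability_R(b, a)$R)
    expect_gte(reliability_R(a, b)$R, 0)
    expect_lte(reliability_R(a, b)$R, 1)
  }

  expect_error(reliability_R(1:3, 1:4), "pairing")
  expect_true(reliability_R(c(2, 2, 2), c(2, 2, 2))$degenerate)
})

test_that("ICC variants match the ANOVA mean-squares oracle", {
  m <- rbind(c(1, 2), c(3, 4), c(5, 6))
  # oracle quantities: MSR = 8, MSC = 1.5, MSE = 0
  agr <- icc_estimate(m, "two-way-agreement")
  expect_equal(agr$MSR, 8); expect_equal(agr$MSC, 1.5)
  expect_equal(agr$MSE, 0, tolerance = 1e-12)
  expect_equal(agr$estimate, 8 / 9, tolerance = 1e-10)
  expect_equal(icc_estimate(m, "two-way-consistency")$estimate, 1,
               tolerance = 1e-10)

  # identical columns give 1 for every variant
  id <- cbind(c(2, 4, 9, 3), c(2, 4, 9, 3), c(2, 4, 9, 3))
  for (v in c("two-way-agreement", "two-way-consistency", "one-way")) {
    expect_equal(icc_estimate(id, v)$estimate, 1, tolerance = 1e-12)
  }
  expect_error(icc_estimate(cbind(c(1, NA), c(2, 3))), "complete")
})

test_that("rater shifts spare the consistency ICC but lower agreement", {
  m <- random_obs_matrix(n = 10, k = 4, seed = 2)
  m2 <- m; m2[, 2] <- m2[, 2] + 1.5
  expect_equal(icc_estimate(m2, "two-way-consistency")$estimate,
               icc_estimate(m, "two-way-consistency")$estimate,
               tolerance = 1e-10)
  expect_lt(icc_estimate(m2, "two-way-agreement")$estimate,
            icc_estimate(m, "two-way-agreement")$estimate)
})

test_that("ICC stays within bounds and brackets its estimate", {
  for (seed in 1:8) {
    m <- random_obs_matrix(n = 12, k = 5, seed = seed)
    r <- icc_estimate(m)
    expect_lte(r$estimate, 1)
    expect_gte(r$estimate, 0)  # positive between-subject variance here
    expect_lte(r$lower, r$estimate)
    expect_gte(r$upper, r$estimate)
    expect_lt(r$p_value, 0.05)  # strong subject separation by design
  }
})
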