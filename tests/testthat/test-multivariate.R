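test_that("PCA reproduces a direct eigen-decomposition of the covariance", {
  set.seed(1)
  x <- matrix(rnorm(80), 10, 8)
  p <- pca_fit(x)
  expect_equal(p$eigenvalues, eigen(cov(x))$values[seq_len(p$k)],
               tolerance = 1e-8)
  expect_equal(crossprod(p$loadings), diag(p$k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-10)
  # deterministic sign convention
  for (j in seq_len(p$k)) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("collinear data load a single component", {
  t <- seq(-1, 1, length.out = 12)
  x <- cbind(t, 2 * t, -0.5 * t)
  p <- pca_fit(x)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  expect_error(pca_fit(x, k = 2), "rank")
})

test_that("LDA achieves perfect accuracy on well-separated classes", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20, 0, 1), 10, 2),
             matrix(rnorm(20, 10, 1), 10, 2))
  labs <- factor(rep(c("p", "q"), each = 10))
  res <- lda_classify(x, labs)
  expect_equal(res$accuracy, 1)
  expect_equal(res$scheme, "leave-one-out")
  expect_equal(sum(res$confusion), 20)

  # brute-force equal-covariance Gaussian discriminant oracle
  # (resubstitution): pooled covariance, equal priors
  res2 <- lda_classify(x, labs, scheme = "resubstitution")
  mus <- rbind(colMeans(x[1:10, ]), colMeans(x[11:20, ]))
  pooled <- (cov(x[1:10, ]) * 9 + cov(x[11:20, ]) * 9) / 18
  pinv <- solve(pooled)
  disc <- apply(x, 1, function(v) {
    d <- c(v - mus[1, ], recursive = TRUE)
    d2 <- c(v - mus[2, ], recursive = TRUE)
    which.min(c(d %*% pinv %*% d, d2 %*% pinv %*% d2))
  })
  expect_equal(as.integer(res2$predicted), as.integer(disc))
})

test_that("permuted labels classify at chance", {
  set.seed(11)
  x <- matrix(rnorm(36 * 3), 36, 3)
  accs <- vapply(1:200, function(i) {
    labs <- factor(sample(rep(1:6, 6)))
    lda_classify(x, labs, scheme = "resubstitution")$accuracy
  }, numeric(1))
  # central 99% binomial band around 1/6 for the mean of 200 runs;
  # resubstitution overfits slightly upward, so bound the mean loosely
  expect_gt(mean(accs), 1 / 6 - 3 * sqrt(1 / 6 * 5 / 6 / (36 * 200)))
  expect_lt(mean(accs), 0.45)
})

test_that("equal priors make the rule insensitive to class duplication", {
  set.seed(5)
  x <- rbind(matrix(rnorm(24, 0, 2), 12, 2),
             matrix(rnorm(24, 3, 2), 12, 2))
  labs <- factor(rep(c("p", "q"), each = 12))
  base <- lda_classify(x, labs, scheme = "resubstitution")
  dup <- rbind(x, x[labs == "q", ])
  dlabs <- factor(c(as.character(labs), rep("q", 12)))
  dres <- lda_classify(dup, dlabs, scheme = "resubstitution")
  expect_equal(as.character(dres$predicted[1:24]),
               as.character(base$predicted))
})

test_that("degenerate within-class scatter falls back to nearest mean", {
  x <- rbind(matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(4, 4), 5), 5, 2, byrow = TRUE))
  labs <- factor(rep(c("p", "q"), each = 5))
  expect_equal(lda_classify(x, labs)$accuracy, 1)
})

test_that("feature counts are capped for a stable covariance", {
  x <- matrix(rnorm(6 * 5), 6, 5)
  expect_error(lda_classify(x, factor(rep(1:2, each = 3))), "fewer PCs")
})

test_that("pc_error_stats reuses the measurement machinery on scores", {
  # identical outlines per tool across observers: perfect agreement
  tools <- factor(rep(1:5, times = 4))
  obs <- factor(rep(1:4, each = 5))
  base <- matrix(rnorm(5 * 3), 5, 3)
  scores <- base[rep(1:5, times = 4), ]
  res <- pc_error_stats(scores, tools, obs, n_pcs = 3)
  expect_true(all(res$pairwise_R == 1))
  expect_equal(res$icc_pooled$estimate, 1, tolerance = 1e-12)
  for (p in 1:3) expect_equal(res$icc_per_pc[[p]]$estimate, 1,
                              tolerance = 1e-12)

  # noisy scores: symmetric R with unit diagonal, ICC in [0, 1]
  noisy <- scores + rnorm(length(scores), 0, 0.1)
  res2 <- pc_error_stats(noisy, tools, obs, n_pcs = 2)
  expect_equal(res2$pairwise_R, t(res2$pairwise_R))
  expect_true(all(diag(res2$pairwise_R) == 1))
  expect_lte(res2$icc_pooled$estimate, 1)

  expect_error(pc_error_stats(scores[-1, ], tools[-1], obs[-1]),
               "balanced")
})

test_that("pooled-score ICC degrades as observer noise grows", {
  tools <- factor(rep(1:6, times = 6))
  obs <- factor(rep(1:6, each = 6))
  base <- matrix(rnorm(6 * 3, 0, 1), 6, 3)
  mean_icc <- function(noise_sd) {
    mean(vapply(1:40, function(s) {
      set.seed(1000 + s)
      sc <- base[rep(1:6, times = 6), ] +
        rnorm(6 * 6 * 3, 0, noise_sd)
      pc_error_stats(sc, tools, obs, n_pcs = 3)$icc_pooled$estimate
    }, numeric(1)))
  }
  iccs <- vapply(c(0.05, 0.1, 0.2, 0.4), mean_icc, numeric(1))
  expect_true(all(diff(iccs) < 0))
})
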