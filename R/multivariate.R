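#' Principal components of a coefficient matrix
#'
#' Covariance-based PCA (centred, unstandardized columns) via
#' [stats::prcomp()], with a deterministic sign convention: within each
#' component the largest-magnitude loading element is made positive.
#'
#' @param x numeric matrix, rows = outlines, columns = flattened EFA
#'   coefficients (or any features).
#' @param k number of components to retain (default: full rank).
#' @return Object of class `pc_model`: list with `center`, `loadings`
#'   (orthonormal columns), `eigenvalues`, `scores` (zero column
#'   means), `variance_fraction` (fractions of total variance, summing
#'   to 1 over the full rank), `k`.
#' @export
pca_fit <- function(x, k = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 rows")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev_all <- pr$sdev^2
  rank <- sum(ev_all > max(ev_all) * 1e-12)
  if (is.null(k)) k <- rank
  if (k > rank) stop(sprintf("k = %d exceeds matrix rank %d", k, rank))
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(center = pr$center, loadings = load,
                 eigenvalues = ev_all[seq_len(k)], scores = scores,
                 variance_fraction = ev_all[seq_len(k)] / sum(ev_all),
                 total_variance = sum(ev_all), rank = rank, k = k),
            class = "pc_model")
}

#' Number of leading PCs reaching a variance fraction
#'
#' @param model a `pc_model`.
#' @param threshold required cumulative variance fraction (default
#'   0.95).
#' @return Smallest number of leading components whose cumulative
#'   variance fraction reaches the threshold.
#' @export
n_pcs_for_variance <- function(model, threshold = 0.95) {
  cf <- cumsum(model$variance_fraction)
  hit <- which(cf >= threshold - 1e-12)
  if (length(hit) == 0) model$k else hit[1]
}

#' Linear discriminant classification of PC scores
#'
#' Equal-covariance Gaussian discriminant (via [MASS::lda()]) with
#' caller-supplied priors — equal priors by default, so that group
#' sample sizes do not inform the rule. Used to ask whether tools are
#' separable by shape (they should be) and whether observers are (they
#' should not be, if inter-observer error is small).
#'
#' @param scores numeric matrix of features (rows = outlines, typically
#'   leading PC scores).
#' @param labels factor of class labels, >= 2 classes, each >= 2
#'   members.
#' @param priors prior probabilities (default: equal, `1/nlevels`).
#' @param scheme `"leave-one-out"` (default) or `"resubstitution"`.
#' @return Object of class `classification_result`: list with
#'   `confusion` (rows = true class), `accuracy`, `priors`, `scheme`.
#' @export
lda_classify <- function(scores, labels, priors = NULL,
                         scheme = c("leave-one-out", "resubstitution")) {
  scheme <- match.arg(scheme)
  scores <- as.matrix(scores)
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2) stop("need >= 2 classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 members")
  if (ncol(scores) > nrow(scores) - g) {
    stop("too many features for a stable pooled covariance; use fewer PCs")
  }
  if (is.null(priors)) priors <- rep(1 / g, g)
  pred <- tryCatch({
    if (scheme == "leave-one-out") {
      MASS::lda(scores, grouping = labels, prior = priors, CV = TRUE)$class
    } else {
      fit <- MASS::lda(scores, grouping = labels, prior = priors)
      stats::predict(fit, scores)$class
    }
  }, error = function(e) {
    # noise-free limit: within-class scatter ~ 0 makes the pooled
    # covariance singular; the discriminant degenerates to nearest
    # class mean, which we apply directly
    wv <- sum(vapply(levels(labels), function(l) {
      sub <- scores[labels == l, , drop = FALSE]
      sum(scale(sub, scale = FALSE)^2)
    }, numeric(1)))
    if (wv < 1e-18 * max(sum(scale(scores, scale = FALSE)^2), 1e-300)) {
      return(nearest_mean_classify(scores, labels, scheme))
    }
    stop("LDA failed (singular pooled covariance?): use fewer PCs [",
         conditionMessage(e), "]")
  })
  confusion <- table(true = labels, predicted = pred)
  structure(list(confusion = confusion,
                 accuracy = mean(pred == labels),
                 predicted = pred,
                 priors = priors, scheme = scheme),
            class = "classification_result")
}

nearest_mean_classify <- function(scores, labels, scheme) {
  n <- nrow(scores)
  pred <- character(n)
  for (i in seq_len(n)) {
    keep <- if (scheme == "leave-one-out") seq_len(n)[-i] else seq_len(n)
    mus <- vapply(levels(labels), function(l) {
      colMeans(scores[keep[labels[keep] == l], , drop = FALSE])
    }, numeric(ncol(scores)))
    d2 <- colSums((matrix(mus, ncol = nlevels(labels)) - scores[i, ])^2)
    pred[i] <- levels(labels)[which.min(d2)]
  }
  factor(pred, levels = levels(labels))
}

#' Observer-error statistics on PC scores
#'
#' Reuses the linear-measurement machinery on shape space: with
#' subjects = tools and raters = observers, computes the ICC of each of
#' the first `n_pcs` score columns, a pooled ICC over (tool, PC) cells,
#' and the pairwise observer reliability matrix with the `n_pcs`
#' dimensions pooled — exactly as the calliper dimensions are pooled
#' for measurements.
#'
#' @param scores PC score matrix (rows = outlines).
#' @param tool_id,observer_id factors labelling rows; the design must
#'   be balanced with one outline per (tool, observer).
#' @param n_pcs number of leading PCs to analyse (default 3).
#' @param variant ICC variant, see [icc_estimate()].
#' @return List with `icc_per_pc` (list of `icc_result`), `icc_pooled`,
#'   `pairwise_R` (K x K matrix), `per_pc_sd` (between-observer sd of
#'   each PC, pooled over tools).
#' @export
pc_error_stats <- function(scores, tool_id, observer_id, n_pcs = 3,
                           variant = "two-way-agreement") {
  scores <- as.matrix(scores)
  tool_id <- factor(tool_id); observer_id <- factor(observer_id)
  if (n_pcs > ncol(scores)) stop("n_pcs exceeds available score columns")
  tab <- table(tool_id, observer_id)
  if (any(tab != 1)) {
    stop("pc_error_stats needs a balanced design with one outline per (tool, observer)")
  }
  nt <- nlevels(tool_id); no <- nlevels(observer_id)
  per_pc <- vector("list", n_pcs)
  stacked <- matrix(NA_real_, nrow = nt * n_pcs, ncol = no,
                    dimnames = list(NULL, levels(observer_id)))
  per_pc_sd <- numeric(n_pcs)
  for (p in seq_len(n_pcs)) {
    m <- matrix(NA_real_, nt, no,
                dimnames = list(levels(tool_id), levels(observer_id)))
    m[cbind(as.integer(tool_id), as.integer(observer_id))] <- scores[, p]
    per_pc[[p]] <- icc_estimate(m, variant = variant)
    stacked[(p - 1) * nt + seq_len(nt), ] <- m
    per_pc_sd[p] <- sqrt(mean(apply(m, 1, stats::var)))
  }
  list(icc_per_pc = per_pc,
       icc_pooled = icc_estimate(stacked, variant = variant),
       pairwise_R = pairwise_reliability(stacked),
       per_pc_sd = per_pc_sd)
}
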