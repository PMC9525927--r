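#' Configuration for a full error analysis run
#'
#' Collects every tunable of the pipeline in one validated object.
#' Exactly one input mode is used: `"synthetic"` (generate an
#' assemblage), `"tps"` (outlines from a TPS file) or `"images"`
#' (silhouette photographs listed in a manifest).
#'
#' @param mode input mode.
#' @param measurements a [measurement_table()] or path to a long-format
#'   measurement CSV (modes `"tps"`/`"images"`; generated in synthetic
#'   mode).
#' @param single_measurements optional second table/CSV of
#'   single-observer repeats for the inter- vs intra-observer
#'   comparison (t/F tables).
#' @param tps_path TPS file (mode `"tps"`).
#' @param image_manifest data frame or CSV path with columns `path`,
#'   `image_id`, `tool_id`, `observer_id`, `px_per_cm` (mode
#'   `"images"`).
#' @param n_tools,n_observers synthetic assemblage size.
#' @param effect an [observer_effect()] (synthetic mode).
#' @param through_images in synthetic mode, rasterize each outline and
#'   re-extract it (exercises the image stage; slower).
#' @param n_points outline resampling density.
#' @param harmonic_threshold cumulative harmonic power required.
#' @param h_max maximum harmonics considered.
#' @param n_pcs_error PCs used for observer-error statistics.
#' @param pc_variance cumulative variance fraction selecting the LDA
#'   feature count.
#' @param icc_variant see [icc_estimate()].
#' @param lda_scheme see [lda_classify()].
#' @param seed RNG seed used for every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "tps", "images"),
                       measurements = NULL, single_measurements = NULL,
                       tps_path = NULL, image_manifest = NULL,
                       n_tools = 6, n_observers = 6,
                       effect = observer_effect(),
                       through_images = FALSE,
                       n_points = 1000, harmonic_threshold = 0.99,
                       h_max = 16, n_pcs_error = 3, pc_variance = 0.95,
                       icc_variant = "two-way-agreement",
                       lda_scheme = "leave-one-out", seed = 1) {
  mode <- match.arg(mode)
  stopifnot(harmonic_threshold > 0, harmonic_threshold <= 1,
            pc_variance > 0, pc_variance <= 1, n_points >= 3, h_max >= 1)
  if (mode == "tps" && is.null(tps_path)) stop("tps mode needs tps_path")
  if (mode == "images" && is.null(image_manifest)) {
    stop("images mode needs image_manifest")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the complete observer-error analysis
#'
#' Executes both arms of the protocol and gathers everything into one
#' report. Outline arm: load or simulate outlines, (optionally) render
#' and re-extract, resample, normalize, elliptic Fourier analysis with
#' harmonic-power selection, PCA, then observer-error statistics on
#' the leading PC scores and equal-prior LDA of tools and observers.
#' Measurement arm: cell summaries, global and per-dimension TEM,
#' %TEM, pairwise observer reliability, ICC (agreement and
#' consistency), Tukey HSD between tools and, when a single-observer
#' table is available, per-cell Welch t and variance-ratio F
#' comparisons. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return List of class `error_report`; see the vignette for the
#'   layout. Includes `provenance` (config, seed, package version).
#' @export
run_error_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(...) message(sprintf(...))

  # ---- acquire outlines and measurements -------------------------------
  if (config$mode == "synthetic") {
    log_stage("simulating %d tools x %d observers (seed %d)",
              config$n_tools, config$n_observers, config$seed)
    arch <- make_archetypes(config$n_tools, seed = config$seed)
    outlines <- simulate_outlines(arch, config$n_observers, config$effect,
                                  seed = config$seed + 1)
    measurements <- simulate_measurements(arch, config$n_observers,
                                          config$effect,
                                          seed = config$seed + 2)
    # single-observer repeats: same protocol, one observer, K replicas
    single <- simulate_measurements(arch, 1, config$effect,
                                    seed = config$seed + 3,
                                    n_replicates = config$n_observers)
    if (config$through_images) {
      log_stage("rasterizing and re-extracting %d outlines",
                length(outlines))
      outlines <- lapply(outlines, function(o) {
        img <- render_image(o, px_per_cm = 60, canvas = c(768, 768))
        apply_scale(binarize_and_extract(img), img$px_per_cm)
      })
    }
  } else {
    measurements <- config$measurements
    if (is.character(measurements)) {
      measurements <- read_measurements(measurements)
    }
    single <- config$single_measurements
    if (is.character(single)) single <- read_measurements(single)
    if (config$mode == "tps") {
      log_stage("reading outlines from %s", config$tps_path)
      outlines <- read_tps(config$tps_path)
    } else {
      man <- config$image_manifest
      if (is.character(man)) man <- utils::read.csv(man)
      log_stage("extracting %d silhouettes", nrow(man))
      outlines <- lapply(seq_len(nrow(man)), function(i) {
        img <- read_silhouette(man$path[i], man$px_per_cm[i],
                               image_id = man$image_id[i],
                               tool_id = man$tool_id[i],
                               observer_id = man$observer_id[i])
        apply_scale(binarize_and_extract(img), img$px_per_cm)
      })
    }
  }

  # ---- outline arm -----------------------------------------------------
  log_stage("resampling to %d points and normalizing", config$n_points)
  norm <- lapply(outlines, function(o) {
    normalize_outline(resample_equidistant(o, config$n_points))
  })
  sel <- vapply(norm, function(o) {
    harmonic_power_select(o, config$harmonic_threshold,
                          config$h_max)$h_selected
  }, numeric(1))
  h_use <- max(sel)
  log_stage("harmonic selection: max over outlines = %d (threshold %.2f)",
            h_use, config$harmonic_threshold)
  coeffs <- lapply(norm, efa_forward, h = h_use)
  cm <- coefficient_matrix(coeffs)
  pca <- pca_fit(cm$x)
  n_feat <- n_pcs_for_variance(pca, config$pc_variance)
  n_feat <- min(n_feat, nrow(cm$x) - max(nlevels(cm$tool_id),
                                         nlevels(cm$observer_id)))
  n_feat <- max(n_feat, 1)
  log_stage("PCA: rank %d; %d PCs retained for LDA", pca$rank, n_feat)
  feats <- pca$scores[, seq_len(n_feat), drop = FALSE]
  lda_tools <- lda_classify(feats, cm$tool_id, scheme = config$lda_scheme)
  lda_obs <- lda_classify(feats, cm$observer_id, scheme = config$lda_scheme)
  pc_err <- pc_error_stats(pca$scores, cm$tool_id, cm$observer_id,
                           n_pcs = min(config$n_pcs_error, pca$k),
                           variant = config$icc_variant)

  # ---- measurement arm -------------------------------------------------
  res_meas <- NULL
  if (!is.null(measurements)) {
    check_balance(measurements)
    summaries <- summarize_cells(measurements, "multiple-observer")
    tem <- compute_tem(measurements)
    om <- observer_matrix(measurements)
    res_meas <- list(
      cell_summaries = summaries,
      tem = tem,
      pairwise_R = pairwise_reliability(om),
      icc_agreement = icc_estimate(om, "two-way-agreement"),
      icc_consistency = icc_estimate(om, "two-way-consistency"),
      tukey = tukey_hsd(measurements)
    )
    if (!is.null(single)) {
      s_sum <- summarize_cells(single, "single-observer")
      res_meas$single_summaries <- s_sum
      key <- paste(summaries$tool_id, summaries$dimension)
      skey <- paste(s_sum$tool_id, s_sum$dimension)
      cmp <- lapply(seq_len(nrow(summaries)), function(i) {
        j <- match(key[i], skey)
        tt <- welch_t_test(summaries$m[i], s_sum$m[j],
                           summaries$sd[i], s_sum$sd[j],
                           summaries$n[i], s_sum$n[j])
        ff <- if (summaries$sd[i] == 0 && s_sum$sd[j] == 0) {
          # degenerate cell pair: identical zero spread, no evidence
          list(F = 1, p_value = 1)
        } else {
          f_variance_test(summaries$sd[i], s_sum$sd[j],
                          summaries$n[i], s_sum$n[j])
        }
        data.frame(tool_id = summaries$tool_id[i],
                   dimension = summaries$dimension[i],
                   t = tt$t, t_p = tt$p_value,
                   F = ff$F, F_p = ff$p_value)
      })
      res_meas$t_f_table <- do.call(rbind, cmp)
    }
  }

  structure(list(
    outlines = list(n = length(outlines), n_points = config$n_points,
                    h_selected = h_use,
                    variance_fraction = pca$variance_fraction,
                    pc_error = pc_err,
                    lda_tools = lda_tools, lda_observers = lda_obs),
    measurements = res_meas,
    provenance = list(config = config[setdiff(names(config),
                                              c("measurements",
                                                "single_measurements"))],
                      seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("morphoerr")))
  ), class = "error_report")
}

#' Write an error report to JSON
#'
#' Serializes the report (full precision) to pretty-printed JSON;
#' matrices become row-major arrays. With `paper_rounding = TRUE` the
#' display convention of published error tables is applied first
#' (means 1 dp, sd/p-values 3 dp, TEM 3 dp).
#'
#' @param report an `error_report`.
#' @param path output path.
#' @param paper_rounding apply display rounding.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(report, path, paper_rounding = FALSE) {
  stopifnot(inherits(report, "error_report"))
  x <- report_to_list(report)
  if (paper_rounding) x <- round_report(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "table")) return(as.data.frame.matrix(x))
    if (is.matrix(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(report)
}

round_report <- function(x, digits = 3) {
  if (is.numeric(x)) return(round(x, digits))
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], round, digits)
    return(x)
  }
  if (is.list(x)) return(lapply(x, round_report, digits = digits))
  x
}
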