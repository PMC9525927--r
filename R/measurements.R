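#' Construct a measurement table
#'
#' A `measurement_table` holds long-format linear measurements of a
#' replicated assemblage: one row per (tool, observer, replicate,
#' dimension) with the recorded value in millimetres. It is the input to
#' [summarize_cells()], [compute_tem()], [pairwise_reliability()] and
#' [icc_estimate()].
#'
#' @param tool_id,observer_id,replicate_id vectors coercible to factor.
#' @param dimension character vector; each entry one of `"length"`,
#'   `"width"`, `"thickness"`.
#' @param value_mm positive numeric measurements in mm.
#' @return A data frame of class `measurement_table` with columns
#'   `tool_id`, `observer_id`, `replicate_id`, `dimension`, `value_mm`.
#' @examples
#' mt <- measurement_table(
#'   tool_id = rep(1, 4), observer_id = rep(c("A", "B"), each = 2),
#'   replicate_id = 1, dimension = rep(c("length", "width"), 2),
#'   value_mm = c(86.2, 40.9, 86.3, 40.8))
#' summarize_cells(mt)
#' @export
measurement_table <- function(tool_id, observer_id, replicate_id,
                              dimension, value_mm) {
  dimension <- as.character(dimension)
  bad <- setdiff(unique(dimension), c("length", "width", "thickness"))
  if (length(bad) > 0) {
    stop("unknown dimension(s): ", paste(bad, collapse = ", "))
  }
  value_mm <- as.numeric(value_mm)
  if (any(!is.finite(value_mm)) || any(value_mm <= 0)) {
    stop("all measurement values must be finite and > 0")
  }
  out <- data.frame(
    tool_id = factor(tool_id),
    observer_id = factor(observer_id),
    replicate_id = factor(replicate_id),
    dimension = factor(dimension, levels = c("length", "width", "thickness")),
    value_mm = value_mm
  )
  out <- out[, c("tool_id", "observer_id", "replicate_id", "dimension",
                 "value_mm")]
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Read a long-format measurement CSV
#'
#' Expects a UTF-8 CSV with header columns `tool_id`, `observer_id`,
#' `replicate_id`, `dimension`, `value_mm`.
#'
#' @param path file path.
#' @return A [measurement_table()].
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("tool_id", "observer_id", "replicate_id", "dimension", "value_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("measurement CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  measurement_table(df$tool_id, df$observer_id, df$replicate_id,
                    df$dimension, df$value_mm)
}

#' Write a measurement table to CSV
#'
#' @param table a [measurement_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Check that a measurement table forms a balanced design
#'
#' A balanced table has every (tool, observer, dimension) cell occupied
#' by the same number of replicates. Most error statistics here (TEM,
#' ICC) require balance.
#'
#' @param table a [measurement_table()].
#' @return `TRUE` invisibly if balanced; otherwise throws an error
#'   naming the first empty cell.
#' @export
check_balance <- function(table) {
  tab <- table(droplevels(table$tool_id), droplevels(table$observer_id),
               droplevels(table$dimension))
  if (any(tab == 0)) {
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unbalanced design: empty cell tool=%s observer=%s dimension=%s",
      dimnames(tab)[[1]][idx[1]], dimnames(tab)[[2]][idx[2]],
      dimnames(tab)[[3]][idx[3]]))
  }
  if (length(unique(as.vector(tab))) > 1) {
    stop("unbalanced design: replicate counts differ between cells")
  }
  invisible(TRUE)
}

#' Summarize measurement cells
#'
#' Computes the mean and sample standard deviation (denominator n - 1)
#' of each (tool, dimension) cell, pooling over observers and
#' replicates. All values are returned at full precision; rounding for
#' display is left to the caller.
#'
#' @param table a [measurement_table()].
#' @param group_tag label stored in the `group` column, e.g.
#'   `"multiple-observer"` or `"single-observer"`.
#' @return Data frame with columns `tool_id`, `dimension`, `group`,
#'   `m` (mean, mm), `sd` (mm) and `n`.
#' @export
summarize_cells <- function(table, group_tag = "multiple-observer") {
  stopifnot(inherits(table, "measurement_table"))
  sp <- split(table$value_mm,
              list(tool = droplevels(table$tool_id),
                   dim = droplevels(table$dimension)), drop = FALSE)
  ns <- vapply(sp, length, integer(1))
  if (any(ns == 0)) {
    stop("empty cell: ", names(sp)[which(ns == 0)[1]])
  }
  if (any(ns < 2)) {
    stop("cell with n < 2 (sd undefined): ", names(sp)[which(ns < 2)[1]])
  }
  key <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  out <- data.frame(
    tool_id = key[, 1],
    dimension = factor(key[, 2], levels = c("length", "width", "thickness")),
    group = group_tag,
    m = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, stats::sd, numeric(1)),
    n = ns,
    row.names = NULL
  )
  out[order(out$tool_id, out$dimension), ]
}

#' Pivot a measurement table to a subjects-by-observers matrix
#'
#' Subjects are (tool, dimension) cells pooled across dimensions, the
#' pooling under which a single global TEM is defined for a calliper
#' study. Requires one replicate per cell.
#'
#' @param table a [measurement_table()].
#' @param dimension optional single dimension to restrict to.
#' @return Numeric matrix, rows = subjects (named `tool.dimension`),
#'   columns = observers.
#' @export
observer_matrix <- function(table, dimension = NULL) {
  stopifnot(inherits(table, "measurement_table"))
  if (!is.null(dimension)) {
    table <- table[table$dimension == dimension, , drop = FALSE]
    table$dimension <- droplevels(table$dimension)
    class(table) <- c("measurement_table", "data.frame")
  }
  check_balance(table)
  obs <- levels(table$observer_id)
  sub <- interaction(table$tool_id, table$dimension, drop = TRUE)
  if (anyDuplicated(paste(sub, table$observer_id))) {
    stop("observer_matrix needs exactly one replicate per (tool, observer, dimension) cell")
  }
  m <- matrix(NA_real_, nrow = nlevels(sub), ncol = length(obs),
              dimnames = list(levels(sub), obs))
  m[cbind(as.integer(sub), as.integer(table$observer_id))] <- table$value_mm
  if (anyNA(m)) stop("unbalanced design: missing cell in observer matrix")
  m
}
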