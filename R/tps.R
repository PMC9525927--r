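#' Read outlines from a TPS coordinate file
#'
#' Parses the plain-text TPS dialect used by the tps software family:
#' records begin with an `LM=` (or `POINTS=`) count line, followed by
#' that many `x y` coordinate pairs and key lines (`IMAGE=`, `ID=`,
#' `SCALE=`, others preserved). `SCALE` (units per pixel) is
#' multiplied into the coordinates on read. A `COMMENT=tool=<t>
#' observer=<o>` key written by [write_tps()] restores tool/observer
#' metadata.
#'
#' @param path TPS file path.
#' @return List of [outline()]s.
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^(LM|POINTS)=", lines, ignore.case = TRUE)
  if (length(starts) == 0) stop("no LM=/POINTS= records found in ", path)
  ends <- c(starts[-1] - 1, length(lines))
  out <- vector("list", length(starts))
  for (rec in seq_along(starts)) {
    block <- lines[starts[rec]:ends[rec]]
    n_declared <- as.integer(sub("^(LM|POINTS)=", "", block[1],
                                 ignore.case = TRUE))
    body <- block[-1]
    is_key <- grepl("^[A-Za-z][A-Za-z0-9_]*=", body)
    coords <- body[!is_key]
    if (length(coords) != n_declared) {
      stop(sprintf(
        "parse error in record %d: declared %d points but found %d",
        rec, n_declared, length(coords)))
    }
    xy <- do.call(rbind, lapply(coords, function(ln) {
      v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
      if (length(v) != 2 || anyNA(v)) {
        stop(sprintf("parse error in record %d: bad coordinate line '%s'",
                     rec, ln))
      }
      v
    }))
    keys <- body[is_key]
    kv <- function(key) {
      hit <- grep(paste0("^", key, "="), keys, ignore.case = TRUE)
      if (length(hit) == 0) NA_character_
      else sub(paste0("^", key, "="), "", keys[hit[1]], ignore.case = TRUE)
    }
    scale <- suppressWarnings(as.numeric(kv("SCALE")))
    if (!is.na(scale)) xy <- xy * scale
    tool <- NA; obs <- NA
    cm <- kv("COMMENT")
    if (!is.na(cm)) {
      m <- regmatches(cm, regexec("tool=([^ ]+) observer=([^ ]+)", cm))[[1]]
      if (length(m) == 3) { tool <- m[2]; obs <- m[3] }
    }
    out[[rec]] <- outline(xy, units = if (is.na(scale)) "px" else "cm",
                          tool_id = tool, observer_id = obs,
                          image_id = kv("IMAGE"))
  }
  out
}

#' Write outlines to a TPS coordinate file
#'
#' One record per outline with fixed field order — count line,
#' coordinate pairs, `IMAGE=`, `ID=`, `SCALE=1.0`, `COMMENT=` with tool
#' and observer — using locale-independent decimal points, so two
#' writes of the same data are byte-identical. Coordinates are written
#' in their stored units with `SCALE=1.0`, making write/read a
#' round trip.
#'
#' @param outlines non-empty list of [outline()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(outlines, path) {
  if (length(outlines) == 0) stop("no outlines to write")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(outlines)) {
    o <- outlines[[i]]
    xy <- as.matrix(o)
    writeLines(sprintf("LM=%d", nrow(xy)), con)
    writeLines(sprintf("%.10g %.10g", xy[, 1], xy[, 2]), con)
    img <- attr(o, "image_id")
    writeLines(sprintf("IMAGE=%s", if (is.na(img)) "" else img), con)
    writeLines(sprintf("ID=%d", i), con)
    writeLines("SCALE=1.0", con)
    writeLines(sprintf("COMMENT=tool=%s observer=%s",
                       attr(o, "tool_id"), attr(o, "observer_id")), con)
  }
  invisible(path)
}
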