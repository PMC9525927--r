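#' Construct an outline
#'
#' An `outline` is an ordered closed sequence of 2D points (the last
#' point connects implicitly back to the first) in a y-up coordinate
#' frame, stored counterclockwise, with optional physical units and
#' tool/observer metadata.
#'
#' @param xy two-column numeric matrix of (x, y) vertices, >= 3 rows,
#'   no two consecutive vertices identical.
#' @param units coordinate units, e.g. `"px"` or `"cm"`.
#' @param tool_id,observer_id,image_id optional metadata.
#' @return Object of class `outline`: the coordinate matrix with
#'   attributes `units`, `tool_id`, `observer_id`, `image_id`.
#' @export
outline <- function(xy, units = "px", tool_id = NA, observer_id = NA,
                    image_id = NA) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 3) stop("outline needs >= 3 (x, y) points")
  if (anyNA(xy) || any(!is.finite(xy))) stop("outline coordinates must be finite")
  dup <- rowSums((xy - xy[c(2:nrow(xy), 1), , drop = FALSE])^2) == 0
  # drop duplicated consecutive vertices (incl. an explicit closing point)
  if (any(dup)) xy <- xy[!dup, , drop = FALSE]
  if (nrow(xy) < 3) stop("outline degenerate after removing duplicate points")
  # enforce counterclockwise orientation, keeping the start point fixed
  if (signed_area(xy) < 0) xy <- xy[c(1, nrow(xy):2), , drop = FALSE]
  dimnames(xy) <- list(NULL, c("x", "y"))
  structure(xy, class = "outline", units = units, tool_id = tool_id,
            observer_id = observer_id, image_id = image_id)
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %d points [%s]  tool=%s observer=%s\n",
              nrow(x), attr(x, "units"), attr(x, "tool_id"),
              attr(x, "observer_id")))
  invisible(x)
}

# shoelace signed area; > 0 for counterclockwise in a y-up frame
signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Outline perimeter
#' @param o an [outline()] or coordinate matrix (closed implicitly).
#' @return Total closed-polygon perimeter.
#' @export
outline_perimeter <- function(o) {
  sum(edge_lengths(as.matrix(o)))
}

edge_lengths <- function(xy) {
  nxt <- xy[c(2:nrow(xy), 1), , drop = FALSE]
  sqrt(rowSums((nxt - xy)^2))
}

#' Outline area (shoelace formula)
#' @param o an [outline()] or coordinate matrix.
#' @return Enclosed area (positive).
#' @export
outline_area <- function(o) {
  abs(signed_area(as.matrix(o)))
}

#' Centroid and centroid size of a point configuration
#'
#' Centroid size here is the root-mean-square distance of the points to
#' their centroid (`sqrt(sum(d^2) / n)`). Any fixed convention cancels
#' when shapes are compared after normalization; this one is used
#' throughout the package.
#'
#' @param o an [outline()] or coordinate matrix.
#' @return `outline_centroid`: length-2 numeric. `centroid_size`: scalar.
#' @export
outline_centroid <- function(o) {
  colMeans(as.matrix(o))
}

#' @rdname outline_centroid
#' @export
centroid_size <- function(o) {
  xy <- as.matrix(o)
  ctr <- colMeans(xy)
  sqrt(sum((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2) / nrow(xy))
}

#' Resample an outline to equidistant points
#'
#' Places `n_points` points equally spaced in arc length along the
#' closed contour, by linear interpolation along the edges. The first
#' output point coincides with the original first vertex.
#'
#' @param o an [outline()] (or coordinate matrix).
#' @param n_points number of points (>= 3).
#' @return An [outline()] with `n_points` points and metadata preserved.
#' @export
resample_equidistant <- function(o, n_points = 1000) {
  if (n_points < 3) stop("n_points must be >= 3")
  xy <- as.matrix(o)
  el <- edge_lengths(xy)
  per <- sum(el)
  if (per <= 0) stop("degenerate outline: zero perimeter")
  s <- c(0, cumsum(el))                      # arc length at each vertex
  target <- per * (seq_len(n_points) - 1) / n_points
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx > nrow(xy)] <- nrow(xy)
  frac <- (target - s[idx]) / el[idx]
  frac[el[idx] == 0] <- 0
  nxt <- c(2:nrow(xy), 1)
  new_xy <- xy[idx, , drop = FALSE] +
    frac * (xy[nxt[idx], , drop = FALSE] - xy[idx, , drop = FALSE])
  outline(new_xy, units = attr(o, "units"), tool_id = attr(o, "tool_id"),
          observer_id = attr(o, "observer_id"), image_id = attr(o, "image_id"))
}

#' Convert pixel coordinates to centimetres
#'
#' Divides coordinates by the image's pixel-per-centimetre ratio.
#'
#' @param o an [outline()] in pixel units.
#' @param px_per_cm positive scale factor (pixels per cm).
#' @return The outline in cm, metadata preserved.
#' @export
apply_scale <- function(o, px_per_cm) {
  if (!is.finite(px_per_cm) || px_per_cm <= 0) {
    stop("px_per_cm must be > 0")
  }
  xy <- as.matrix(o) / px_per_cm
  outline(xy, units = "cm", tool_id = attr(o, "tool_id"),
          observer_id = attr(o, "observer_id"), image_id = attr(o, "image_id"))
}
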