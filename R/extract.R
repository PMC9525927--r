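#' Construct a silhouette image
#'
#' Wraps an intensity matrix (values in [0, 1], rows running top to
#' bottom as in raster files) together with its physical scale and
#' identifying metadata.
#'
#' @param intensity numeric matrix in [0, 1].
#' @param px_per_cm positive pixels-per-centimetre scale.
#' @param image_id,tool_id,observer_id optional metadata.
#' @return Object of class `silhouette_image`.
#' @export
silhouette_image <- function(intensity, px_per_cm, image_id = NA,
                             tool_id = NA, observer_id = NA) {
  m <- as.matrix(intensity)
  if (length(m) == 0) stop("empty image")
  if (!is.finite(px_per_cm) || px_per_cm <= 0) stop("px_per_cm must be > 0")
  structure(list(intensity = m, px_per_cm = px_per_cm,
                 image_id = image_id, tool_id = tool_id,
                 observer_id = observer_id),
            class = "silhouette_image")
}

#' Read a silhouette photograph
#'
#' Reads PNG or TIFF via the \pkg{png} / \pkg{tiff} packages (JPEG via
#' \pkg{EBImage} when installed); RGB images are converted to luminance
#' (Rec. 709 weights).
#'
#' @param path image file.
#' @param px_per_cm pixels-per-centimetre scale for this image.
#' @param image_id,tool_id,observer_id optional metadata (default
#'   `image_id` is the file name).
#' @return A [silhouette_image()].
#' @export
read_silhouette <- function(path, px_per_cm, image_id = basename(path),
                            tool_id = NA, observer_id = NA) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("reading JPEG requires the EBImage package")
      }
      im <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores x-by-y; transpose to row-by-column
      if (length(dim(im)) == 3) aperm(im, c(2, 1, 3)) else t(im)
    },
    stop("unsupported image format: ", ext)
  )
  silhouette_image(luminance(arr), px_per_cm, image_id = image_id,
                   tool_id = tool_id, observer_id = observer_id)
}

luminance <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  if (dim(arr)[3] >= 3) {
    0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  } else {
    arr[, , 1]
  }
}

#' Extract the object contour from a silhouette image
#'
#' Traces the sub-pixel iso-contour of the foreground at a threshold
#' fraction of the image's intensity range (marching-squares style, via
#' [grDevices::contourLines()]), keeps the closed contour enclosing the
#' largest area, and returns it in a y-up coordinate frame with
#' counterclockwise orientation. Pixel centres sit at integer
#' coordinates (0-based); contour vertices fall at iso-crossings between
#' pixels.
#'
#' Hard binary masks make marching squares staircase (iso-crossings sit
#' at pixel-edge midpoints), which inflates the traced perimeter by a
#' few percent while leaving the area nearly exact. A light separable
#' binomial blur (`smooth_passes` applications of a 1-2-1 kernel)
#' spreads each edge over neighbouring pixels so the linear
#' interpolation recovers sub-pixel crossings; `smooth_passes = 0`
#' gives the raw pixel-boundary-style trace.
#'
#' @param img a [silhouette_image()].
#' @param threshold threshold as a fraction of the intensity range, in
#'   (0, 1); default 0.5.
#' @param foreground `"dark"` (default: dark object on light ground) or
#'   `"light"`.
#' @param smooth_passes binomial smoothing passes before contouring.
#' @return Raw contour polyline: an [outline()] in pixel units (not yet
#'   resampled or scaled), metadata copied from the image.
#' @export
binarize_and_extract <- function(img, threshold = 0.5,
                                 foreground = c("dark", "light"),
                                 smooth_passes = 2) {
  stopifnot(inherits(img, "silhouette_image"))
  foreground <- match.arg(foreground)
  m <- img$intensity
  score <- if (foreground == "dark") max(m) - m else m - min(m)
  for (i in seq_len(smooth_passes)) score <- binomial_blur(score)
  rng <- diff(range(score))
  if (rng == 0) stop("empty mask: image has no foreground component")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  level <- threshold * rng

  nr <- nrow(m); nc <- ncol(m)
  # orient to math coordinates: dim 1 = x (column), dim 2 = y (y-up)
  z <- t(score)[, nr:1, drop = FALSE]
  cl <- grDevices::contourLines(x = 0:(nc - 1), y = 0:(nr - 1), z = z,
                                levels = level)
  closed <- Filter(function(cc) {
    n <- length(cc$x)
    n >= 4 && cc$x[1] == cc$x[n] && cc$y[1] == cc$y[n]
  }, cl)
  if (length(closed) == 0) {
    stop("empty mask: no closed foreground contour at this threshold")
  }
  areas <- vapply(closed, function(cc) {
    n <- length(cc$x)
    abs(signed_area(cbind(cc$x[-n], cc$y[-n])))
  }, numeric(1))
  if (length(areas) > 1 && sort(areas, decreasing = TRUE)[2] > 0.5 * max(areas)) {
    warning("multiple similar-size foreground components; keeping the largest")
  }
  best <- closed[[which.max(areas)]]
  n <- length(best$x)
  outline(cbind(best$x[-n], best$y[-n]), units = "px",
          tool_id = img$tool_id, observer_id = img$observer_id,
          image_id = img$image_id)
}

# separable 1-2-1 binomial blur with replicated edges
binomial_blur <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  m <- (p[1:nr, , drop = FALSE] + 2 * p[2:(nr + 1), , drop = FALSE] +
          p[3:(nr + 2), , drop = FALSE]) / 4
  p <- cbind(m[, 1, drop = FALSE], m, m[, nc, drop = FALSE])
  (p[, 1:nc, drop = FALSE] + 2 * p[, 2:(nc + 1), drop = FALSE] +
      p[, 3:(nc + 2), drop = FALSE]) / 4
}
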