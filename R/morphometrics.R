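## Dropout area and per-gland morphometrics.

# Moment-matched ellipse of a pixel set: axis lengths (px) and orientation
# (degrees, vertical = 90). Axis lengths are 4*sqrt(eigenvalue) of the
# pixel covariance (with the 1/12 unit-pixel term), which reproduces the
# shape itself for filled ellipses.
moment_ellipse <- function(pixels) {
  if (nrow(pixels) < 3L)
    degenerate_object_error("moment ellipse needs at least 3 pixels")
  x <- pixels[, 2]; y <- -pixels[, 1]
  cx <- x - mean(x); cy <- y - mean(y)
  sxx <- mean(cx * cx) + 1 / 12
  syy <- mean(cy * cy) + 1 / 12
  sxy <- mean(cx * cy)
  tr <- sxx + syy
  det_ <- sxx * syy - sxy * sxy
  disc <- sqrt(max(tr * tr / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  theta <- (0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi) %% 180
  list(length = 4 * sqrt(l1), width = 4 * sqrt(max(l2, 0)),
       orientation_deg = theta,
       # 0-based image coordinates
       centroid = c(x = mean(pixels[, 2]) - 1, y = mean(pixels[, 1]) - 1))
}

#' Moment-ellipse metrics of a single gland
#'
#' Fits the ellipse with the same normalized second central moments as the
#' gland; its major and minor axis lengths are the gland length and width.
#'
#' @param pixels two-column (row, col) index matrix of the gland pixels
#'   (1-based) or a logical mask matrix.
#' @param mm_per_px pixel scale for the millimetre values.
#' @return List with `length_px`, `width_px`, `length_mm`, `width_mm`,
#'   `orientation_deg`, `centroid_x` (0-based column).
#' @export
gland_ellipse_metrics <- function(pixels, mm_per_px = 0.02) {
  if (is.logical(pixels) && is.matrix(pixels))
    pixels <- which(pixels, arr.ind = TRUE)
  m <- moment_ellipse(pixels)
  list(
    length_px = m$length, width_px = m$width,
    length_mm = m$length * mm_per_px, width_mm = m$width * mm_per_px,
    orientation_deg = m$orientation_deg,
    centroid_x = unname(m$centroid["x"])
  )
}

#' Estimate the gland region (glands + intergland tissue)
#'
#' Morphological closing of the binary gland mask with a disk structuring
#' element. Intergland gaps narrower than about twice the disk radius are
#' filled (healthy tissue), while wide background areas -- true dropout --
#' stay open. The result is intersected with the ROI.
#'
#' An alternative mean-filter route (`method = "meanfilter"`: disk mean
#' filter followed by thresholding at 0.5) is available behind the
#' configuration switch.
#'
#' @param gland_mask logical matrix of segmented gland pixels.
#' @param roi an `mg_roi`.
#' @param disk_radius disk radius in px (default 20, the mean gland
#'   width for the reference device).
#' @param method `"closing"` (default) or `"meanfilter"`.
#' @return List with `mask` (logical matrix) and `n_px_gl` (pixel count).
#' @export
estimate_gland_region <- function(gland_mask, roi, disk_radius = 20L,
                                  method = c("closing", "meanfilter")) {
  method <- match.arg(method)
  if (!all(dim(gland_mask) == dim(roi$mask)))
    parameter_error("gland mask and ROI dimensions differ")
  if (!any(gland_mask))
    return(list(mask = gland_mask & FALSE, n_px_gl = 0L))
  brush <- EBImage::makeBrush(2L * disk_radius + 1L, "disc")
  closed <- if (method == "closing") {
    EBImage::closing(gland_mask * 1, brush) > 0.5
  } else {
    EBImage::filter2(gland_mask * 1, brush / sum(brush)) > 0.5
  }
  m <- closed & roi$mask
  list(mask = m, n_px_gl = sum(m))
}

#' Detect specular reflections inside the ROI
#'
#' Pixels of the original grayscale image strictly brighter than the
#' threshold (default 200 on the 0-255 scale) inside the ROI.
#'
#' @param gray intensity matrix (0-255).
#' @param roi an `mg_roi`.
#' @param threshold intensity cut (strict inequality).
#' @return List with `mask` and `n_px_r`.
#' @export
detect_reflections <- function(gray, roi, threshold = 200) {
  m <- (gray > threshold) & roi$mask
  list(mask = m, n_px_r = sum(m))
}

#' Dropout-area percentage
#'
#' `DOA = 100 * (N_pxROI - N_pxGL - N_pxR) / N_pxROI`, where `N_pxROI` is
#' the ROI pixel count, `N_pxGL` the pixel count of the estimated gland
#' region (glands plus intergland tissue) and `N_pxR` the specular
#' reflection pixel count.
#'
#' @param n_px_roi,n_px_gl,n_px_r nonnegative pixel counts.
#' @return List of class `mg_doa` with the three counts and `doa_percent`.
#' @export
compute_doa <- function(n_px_roi, n_px_gl, n_px_r = 0L) {
  if (n_px_roi <= 0)
    invalid_counts_error("ROI pixel count must be positive")
  if (n_px_gl < 0 || n_px_r < 0 || n_px_gl + n_px_r > n_px_roi)
    invalid_counts_error("gland + reflection pixels exceed the ROI")
  structure(
    list(n_px_roi = n_px_roi, n_px_gl = n_px_gl, n_px_r = n_px_r,
         doa_percent = 100 * (n_px_roi - n_px_gl - n_px_r) / n_px_roi),
    class = "mg_doa"
  )
}

#' @export
print.mg_doa <- function(x, ...) {
  cat(sprintf("<mg_doa> %.2f%% (ROI %d px, glands %d px, reflections %d px)\n",
              x$doa_percent, x$n_px_roi, x$n_px_gl, x$n_px_r))
  invisible(x)
}

#' Relative gland length
#'
#' Gland length as a percentage of the local eyelid height, evaluated at
#' the gland centroid column from the fitted boundary curves (or the mask
#' column extent for manual ROIs). Values above 100 are possible for
#' oblique glands and are flagged with a warning downstream.
#'
#' @param length_px gland length in px (moment-ellipse major axis).
#' @param roi an `mg_roi`.
#' @param centroid_column 0-based gland centroid column.
#' @return Percentage.
#' @export
relative_length <- function(length_px, roi, centroid_column) {
  if (centroid_column < 0 || centroid_column > ncol(roi$mask) - 1)
    outside_roi_error("centroid column outside the image")
  h <- roi_height_at(roi, centroid_column)
  100 * length_px / h
}
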