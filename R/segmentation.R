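## Meibomian gland segmentation inside the ROI.

#' Difference-of-Gaussians band-pass filter
#'
#' The grayscale image is convolved in parallel with a narrow (sigma = 2
#' px) and a wide (sigma = 30 px) Gaussian kernel and the wide response is
#' subtracted from the narrow one. The band-pass enhances structures at
#' the gland width scale without amplifying pixel noise.
#'
#' @param gray intensity matrix (any scale; the response keeps it).
#' @param sigma_low,sigma_high Gaussian standard deviations in px;
#'   `sigma_low < sigma_high`.
#' @return Real-valued matrix (zero-mean for constant input).
#' @export
bandpass_dog <- function(gray, sigma_low = 2, sigma_high = 30) {
  if (sigma_low >= sigma_high)
    parameter_error("sigma_low must be smaller than sigma_high")
  # cap the kernel support on small inputs (filter kernels cannot exceed
  # the image size)
  rad <- function(s) {
    r <- 2L * as.integer(ceiling(3 * s)) + 1L
    lim <- min(dim(gray))
    if (r > lim) r <- lim - (1L - lim %% 2L)
    r
  }
  lo <- EBImage::gblur(gray, sigma_low, radius = rad(sigma_low))
  hi <- EBImage::gblur(gray, sigma_high, radius = rad(sigma_high))
  unclass(lo - hi)
}

#' Segment glands inside the ROI
#'
#' The band-passed image is masked by the ROI, binarized with a locally
#' adaptive threshold (local mean over `adaptive_window`, shifted by the
#' sensitivity so that higher sensitivity marks more pixels as
#' foreground), smoothed with a 5 x 3 px median (majority) filter, and
#' cleaned by removing components below `min_gland_px` and components
#' whose moment-ellipse orientation is outside [40 deg, 140 deg] (glands
#' run vertically; horizontal structures are eyelid edges).
#'
#' @param bandpassed output of [bandpass_dog()].
#' @param roi an `mg_roi` (see [select_roi()]).
#' @param sensitivity adaptive-threshold sensitivity in [0, 1]; the local
#'   threshold is `local_mean + (1 - sensitivity) * q95` where `q95` is
#'   the 95th percentile of the absolute band-pass deviation from the
#'   local mean inside the ROI (the strong-signal level). Higher
#'   sensitivity lowers the threshold and marks more pixels as
#'   foreground; the offset stays above the noise floor so texture-free
#'   dropout does not fill with speckle.
#' @param min_gland_px minimum component size in px.
#' @param adaptive_window local-mean window side in px; must exceed the
#'   gland-plus-intergland period so a gland cannot suppress its own
#'   threshold (default 75 for ~20 px glands spaced ~50 px apart).
#' @param orientation_min,orientation_max allowed moment-ellipse
#'   orientations in degrees (vertical = 90).
#' @param rim_px foreground is suppressed within this distance of the ROI
#'   boundary: the boundary step itself produces band-pass response that
#'   would otherwise bridge neighbouring glands into one component.
#' @return Logical matrix of gland pixels (subset of the ROI mask).
#' @export
segment_glands <- function(bandpassed, roi, sensitivity = 0.7,
                           min_gland_px = 800L, adaptive_window = 75L,
                           orientation_min = 40, orientation_max = 140,
                           rim_px = 5L) {
  if (is.null(roi$mask) || !any(roi$mask))
    empty_roi_error("ROI mask is empty")
  if (!all(dim(bandpassed) == dim(roi$mask)))
    parameter_error("band-passed image and ROI dimensions differ")
  r <- as.integer(adaptive_window / 2)
  # ROI-masked local mean: an unmasked mean would be dragged down by the
  # band-pass halo outside the ROI boundary and overdetect along the rim
  M <- roi$mask
  lm_ <- box_sum(bandpassed * M, r, r) / pmax(box_sum(M * 1, r, r), 1)
  dev <- bandpassed - lm_
  q95 <- stats::quantile(abs(dev[M]), 0.95, names = FALSE)
  inner <- if (rim_px > 0L) box_sum((!M) * 1, rim_px, rim_px) == 0 else M
  fg <- (dev > (1 - sensitivity) * q95) & inner
  fg <- majority_filter(fg, 2L, 1L) & inner    # 5 x 3 median
  lab <- label8(fg)
  sizes <- label_sizes(lab)
  if (length(sizes) == 0L) return(fg & FALSE)
  keep <- sizes >= min_gland_px
  for (l in which(keep)) {
    ang <- tryCatch(object_orientation(which(lab == l, arr.ind = TRUE)),
                    degenerate_object_error = function(e) NA_real_)
    if (is.na(ang) || ang < orientation_min || ang > orientation_max)
      keep[l] <- FALSE
  }
  filter_labels(lab, keep)
}

#' Orientation of a pixel set
#'
#' Orientation of the major axis of the ellipse with the same normalized
#' second central moments as the object, measured from the +x axis with y
#' increasing downward folded into [0, 180); a vertical gland scores 90.
#'
#' @param pixels two-column matrix of (row, col) indices (1-based, as from
#'   `which(..., arr.ind = TRUE)`).
#' @return Angle in degrees in [0, 180).
#' @export
object_orientation <- function(pixels) {
  if (nrow(pixels) < 3L)
    degenerate_object_error("orientation needs at least 3 pixels")
  x <- pixels[, 2]; y <- -pixels[, 1]   # flip y so angles read the usual way
  cx <- x - mean(x); cy <- y - mean(y)
  # 1/12 term: second moment of a unit pixel, as in moment-based regionprops
  sxx <- mean(cx * cx) + 1 / 12
  syy <- mean(cy * cy) + 1 / 12
  sxy <- mean(cx * cy)
  if (sxx + syy <= 1e-12)
    degenerate_object_error("object has no spatial extent")
  theta <- 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  theta %% 180
}

mg_labelmap <- function(labels) {
  structure(
    list(labels = labels, n_glands = max(labels)),
    class = "mg_labelmap"
  )
}

#' @export
print.mg_labelmap <- function(x, ...) {
  cat(sprintf("<mg_labelmap> %d glands, %d labelled px\n",
              x$n_glands, sum(x$labels > 0)))
  invisible(x)
}

#' Label segmented glands
#'
#' 8-connected components of the binary gland mask are labelled and
#' renumbered left-to-right by centroid column.
#'
#' @param mask logical matrix of gland pixels.
#' @return An `mg_labelmap` with consecutive labels 1..n ordered by
#'   centroid column.
#' @export
label_glands <- function(mask) {
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) return(mg_labelmap(lab))
  mg_labelmap(relabel_by_column(lab))
}

# Renumber a label matrix so labels run left-to-right by centroid column.
relabel_by_column <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(lab)
  cols <- matrix(rep(seq_len(ncol(lab)), each = nrow(lab)), nrow(lab))
  cx <- vapply(seq_len(n), function(l) mean(cols[lab == l]), numeric(1))
  ord <- order(cx)
  lut <- integer(n); lut[ord] <- seq_len(n)
  matrix(c(0L, lut)[lab + 1L], nrow(lab), ncol(lab))
}
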