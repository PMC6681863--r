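## Tarsal-conjunctiva ROI detection.
##
## The tarsal conjunctiva is located by detecting the upper and lower
## boundaries of the everted eyelid on separate subimages, filling the
## region between the fitted curves, and refining it with Chan-Vese active
## contouring on a local-standard-deviation transform.

#' Split an eyelid image at the bright tarsal band
#'
#' The grayscale image is split in two by exploring mean intensity along y:
#' the row-mean profile is smoothed with a moving average and the split is
#' placed at its argmax, which lies inside the bright tarsal band between
#' the two eyelid boundaries.
#'
#' @param image an [mg_image].
#' @param smooth_rows moving-average window (rows) for the row-mean profile.
#' @param peak_margin minimum excess (intensity units) of the profile peak
#'   over the profile median; below this the acquisition is considered
#'   unusable and a `flat_image_error` is raised.
#' @return List with `upper_subimage`, `lower_subimage` (matrices) and
#'   `split_row` (0-based row index; the lower subimage starts there).
#' @export
split_eyelid_image <- function(image, smooth_rows = 31L, peak_margin = 10) {
  px <- image$pixels
  prof <- rowMeans(px)
  k <- rep(1 / smooth_rows, smooth_rows)
  sm <- stats::filter(prof, k, sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  sm <- as.numeric(sm)
  if (max(sm) < stats::median(sm) + peak_margin)
    flat_image_error("no tarsal band: row-mean profile has no usable peak")
  split_row <- which.max(sm) - 1L   # 0-based
  if (split_row <= 0L || split_row >= image$height_px - 1L)
    flat_image_error("tarsal band peak lies at the image border")
  list(
    upper_subimage = px[seq_len(split_row), , drop = FALSE],
    lower_subimage = px[(split_row + 1L):image$height_px, , drop = FALSE],
    split_row = split_row
  )
}

#' Detect the upper eyelid boundary
#'
#' Pipeline on the upper subimage: disk erosion (r = 10 px), unsharp
#' sharpening built from a Gaussian low-pass (sigma = 30 px), 40 x 40 px
#' median filtering, Otsu binarization, horizontal Sobel edge detection,
#' removal of edge components below `min_edge_px`, and a quadratic fit per
#' surviving edge. The curve with the smallest strictly positive quadratic
#' coefficient is returned (the everted upper boundary is convex).
#'
#' @param upper_subimage matrix of intensities (0-255), rows = y.
#' @param min_edge_px minimum pixel count for an edge component.
#' @param erode_radius disk radius for the initial erosion.
#' @param sharpen_sigma Gaussian sigma of the low-pass used for unsharp
#'   masking.
#' @param sharpen_amount unsharp gain.
#' @param median_size median-filter neighbourhood side (px).
#' @return An `mg_boundary` of kind `quadratic` (full-image coordinates).
#' @export
detect_upper_boundary <- function(upper_subimage, min_edge_px = 500L,
                                  erode_radius = 10L, sharpen_sigma = 30,
                                  sharpen_amount = 1, median_size = 40L) {
  if (nrow(upper_subimage) < 40L)
    parameter_error("upper subimage must be at least 40 px tall")
  x <- upper_subimage / 255
  x <- EBImage::erode(x, EBImage::makeBrush(2L * erode_radius + 1L, "disc"))
  x <- x + sharpen_amount * (x - EBImage::gblur(x, sharpen_sigma))
  x <- pmin(pmax(x, 0), 1)
  x <- EBImage::medianFilter(x, max(1L, as.integer(median_size / 2)))
  bw <- x > EBImage::otsu(x)
  sob <- rbind(c(-1, -2, -1), c(0, 0, 0), c(1, 2, 1))
  # replicate padding: circular padding would fabricate border edges
  mag <- abs(EBImage::filter2(bw * 1, sob, boundary = "replicate"))
  edges <- mag > 0.5
  lab <- label8(edges)
  sizes <- label_sizes(lab)
  keep <- which(sizes >= min_edge_px)
  if (length(keep) == 0L)
    no_boundary_error("no edge component survives the size filter")
  fits <- lapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    fit_quadratic(idx[, 2] - 1, idx[, 1] - 1)   # x = col, y = row, 0-based
  })
  a2 <- vapply(fits, function(f) f$coefficients[3], numeric(1))
  pos <- which(a2 > 1e-9)
  if (length(pos) == 0L)
    no_boundary_error("no fitted edge has a positive quadratic coefficient")
  best <- fits[[pos[which.min(a2[pos])]]]
  # the disk erosion displaces the top edge of the bright band downward by
  # exactly its radius; undo that known offset
  best$coefficients[1] <- best$coefficients[1] - erode_radius
  best
}

#' Detect the lower eyelid boundary
#'
#' Pipeline on the lower subimage: local entropy filter (9 x 9 px),
#' per-column intensity-peak detection on the entropy response, dilation
#' with a horizontal 3 x 12 px rectangle, closing with a disk (r = 6 px),
#' removal of components below `min_obj_px`, selection of the component
#' with the largest horizontal extent, and a constrained degree-4 Chebyshev
#' fit (degree-4 coefficient <= 0, concave shape) of that component's lower
#' edge.
#'
#' @param lower_subimage matrix of intensities (0-255), rows = y.
#' @param min_obj_px minimum pixel count for a candidate component.
#' @param entropy_radius half-size of the entropy neighbourhood (4 -> 9x9).
#' @param peak_frac per-column peak threshold as a fraction of the column's
#'   entropy dynamic range; peaks below `col_min + peak_frac * col_range`
#'   are treated as background noise.
#' @param row_offset added to fitted rows so the curve lives in full-image
#'   coordinates (pass the split row).
#' @return An `mg_boundary` of kind `chebyshev4`.
#' @export
detect_lower_boundary <- function(lower_subimage, min_obj_px = 500L,
                                  entropy_radius = 4L, peak_frac = 0.5,
                                  row_offset = 0L) {
  if (ncol(lower_subimage) < 12L)
    parameter_error("lower subimage must be at least 12 px wide")
  ent <- local_entropy(lower_subimage, entropy_radius)
  up <- shift_mat(ent, 1L, 0L)    # value above
  dn <- shift_mat(ent, -1L, 0L)   # value below
  cmin <- matrix(apply(ent, 2, min), nrow(ent), ncol(ent), byrow = TRUE)
  cmax <- matrix(apply(ent, 2, max), nrow(ent), ncol(ent), byrow = TRUE)
  peaks <- (ent > up) & (ent >= dn) & (ent >= cmin + peak_frac * (cmax - cmin))
  pk <- EBImage::dilate(peaks * 1, matrix(1, 3, 12))
  pk <- EBImage::closing(pk, EBImage::makeBrush(13L, "disc"))
  lab <- label8(pk > 0.5)
  sizes <- label_sizes(lab)
  keep <- which(sizes >= min_obj_px)
  if (length(keep) == 0L)
    no_boundary_error("no component survives the size filter")
  extent <- vapply(keep, function(l) {
    cols <- which(colSums(lab == l) > 0)
    diff(range(cols)) + 1L
  }, numeric(1))
  l <- keep[which.max(extent)]
  obj <- lab == l
  cols <- which(colSums(obj) > 0)
  bottom <- vapply(cols, function(j) max(which(obj[, j])), numeric(1))
  # robust fit: stray entropy blobs merged into the component would
  # otherwise drag the lower edge down
  fit_chebyshev4_robust(cols - 1, bottom - 1 + row_offset)
}

#' Fill the region between two fitted boundary curves
#'
#' Pixel (x, y) is inside iff `upper(x) <= y < lower(x)` on the overlapping
#' column domain (0-based coordinates, half-open rows).
#'
#' @param upper,lower `mg_boundary` curves in full-image coordinates.
#' @param shape integer c(height, width) of the output mask.
#' @return Logical matrix.
#' @export
build_initial_mask <- function(upper, lower, shape) {
  h <- shape[1]; w <- shape[2]
  x0 <- max(upper$domain[1], lower$domain[1], 0)
  x1 <- min(upper$domain[2], lower$domain[2], w - 1)
  if (x1 < x0)
    empty_mask_error("boundary curves have no overlapping column domain")
  xs <- seq(ceiling(x0), floor(x1))
  yu <- eval_boundary(upper, xs)
  yl <- eval_boundary(lower, xs)
  ys <- 0:(h - 1)
  sub <- outer(ys, yu, ">=") & outer(ys, yl, "<")
  mask <- matrix(FALSE, h, w)
  mask[, xs + 1L] <- sub
  if (!any(mask))
    empty_mask_error("upper boundary lies below the lower boundary everywhere")
  mask
}

#' Refine an ROI mask with Chan-Vese active contouring
#'
#' The two-phase Chan-Vese model is evolved on the 9 x 9 local-standard-
#' deviation transform of the image (the tarsal band is textured by the
#' glands, the surround is smooth), seeded with `initial_mask`. A discrete
#' narrow-band scheme is used: at each iteration the region means inside
#' and outside the current mask are recomputed and only pixels adjacent to
#' the contour may switch sides, followed by a 3 x 3 majority smoothing
#' (curvature regularization). Interior pixels far from the contour keep
#' their seed labels, so enclosed dropout regions stay inside the ROI.
#'
#' @param image an [mg_image].
#' @param initial_mask logical matrix seed.
#' @param iterations maximum number of iterations (0 returns the seed
#'   unchanged).
#' @param sd_radius half-size of the local-SD neighbourhood (4 -> 9x9).
#' @param tol convergence: fraction of the mask area that may change
#'   between checkpoints.
#' @param check_every checkpoint spacing in iterations.
#' @param max_displacement_px the contour may move at most this far
#'   (Chebyshev distance) from the seed contour. The refinement corrects
#'   the fitted boundary curves locally; an unbounded region competition
#'   would also carve texture-free dropout out of the ROI rim, which must
#'   stay inside the ROI.
#' @return Logical matrix: the largest 8-connected component of the
#'   converged region.
#' @export
refine_roi_chan_vese <- function(image, initial_mask, iterations = 60L,
                                 sd_radius = 4L, tol = 0.001,
                                 check_every = 5L,
                                 max_displacement_px = 25L) {
  if (!any(initial_mask))
    empty_mask_error("initial mask is empty")
  if (iterations <= 0L)
    return(initial_mask)
  # work on the padded bounding box of the seed
  idx <- which(initial_mask, arr.ind = TRUE)
  pad <- 60L
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(initial_mask), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(initial_mask), max(idx[, 2]) + pad)
  crop <- image$pixels[r0:r1, c0:c1, drop = FALSE]
  f <- local_sd(crop, sd_radius)
  phi <- initial_mask[r0:r1, c0:c1, drop = FALSE]
  # specular reflections are saturated, texture-free patches of tarsal
  # tissue; left as-is they read as "outside" and get notched out of the
  # contour, so their feature value is pinned to the seed-region mean
  refl <- box_sum((crop > 200) * 1, sd_radius, sd_radius) > 0
  if (any(refl)) f[refl] <- mean(f[phi])
  # evolution is confined to a band around the seed contour
  d <- max_displacement_px
  near_out <- box_sum(phi * 1, d, d) > 0          # within d of the region
  near_in <- box_sum((!phi) * 1, d, d) > 0        # within d of the outside
  frozen <- which(!(near_out & near_in))
  seed_vals <- phi[frozen]
  prev <- phi
  for (it in seq_len(iterations)) {
    c1m <- mean(f[phi])
    c2m <- if (all(phi)) 0 else mean(f[!phi])
    # one 3x3 box sum gives the contour band and the majority smoothing
    bs <- box_sum(phi * 1, 1L, 1L)
    band <- bs > 0 & bs < 9            # pixels adjacent to the contour
    pref <- (f - c1m)^2 < (f - c2m)^2
    phi[band] <- pref[band]
    phi <- box_sum(phi * 1, 1L, 1L) >= 5   # 3x3 majority (curvature)
    phi[frozen] <- seed_vals               # displacement cap
    if (it %% check_every == 0L) {
      changed <- sum(xor(phi, prev))
      if (changed < tol * max(1L, sum(phi))) break
      prev <- phi
    }
  }
  # the local-SD transform responds within sd_radius of the true texture
  # edge, so the converged contour overshoots outward by about that much;
  # erode by the window radius to undo the known halo
  phi <- box_sum((!phi) * 1, sd_radius, sd_radius) == 0
  out <- matrix(FALSE, nrow(initial_mask), ncol(initial_mask))
  out[r0:r1, c0:c1] <- phi
  largest_component(out)
}

mg_roi <- function(mask, upper = NULL, lower = NULL,
                   status = c("auto", "manual", "failed"), error = NULL) {
  status <- match.arg(status)
  structure(
    list(mask = mask, upper = upper, lower = lower, status = status,
         area_px = if (is.null(mask)) 0L else sum(mask), error = error),
    class = "mg_roi"
  )
}

#' @export
print.mg_roi <- function(x, ...) {
  cat(sprintf("<mg_roi> status=%s, area=%d px%s\n", x$status, x$area_px,
              if (!is.null(x$error)) paste0(" (", x$error$class, ")") else ""))
  invisible(x)
}

#' Select the tarsal-conjunctiva ROI
#'
#' Orchestrates the automatic ROI pipeline (split, upper/lower boundary
#' detection, initial mask, Chan-Vese refinement). If a manual polygon is
#' supplied it is rasterized instead (`status = "manual"`). Stage failures
#' never escape: the result carries `status = "failed"` with the causal
#' condition recorded, so batch processing can continue.
#'
#' @param image an [mg_image].
#' @param manual_polygon optional two-column matrix of 0-based `x,y`
#'   polygon vertices (see [read_roi_polygon]).
#' @param config an [mg_config] parameter list.
#' @return An `mg_roi` with fields `mask`, `upper`, `lower`, `status`,
#'   `area_px`.
#' @export
select_roi <- function(image, manual_polygon = NULL, config = mg_config()) {
  if (!is.null(manual_polygon)) {
    mask <- rasterize_polygon(manual_polygon, image$height_px, image$width_px)
    return(mg_roi(mask, status = "manual"))
  }
  p <- config$roi
  res <- tryCatch({
    sp <- split_eyelid_image(image, p$split_smooth_rows, p$split_peak_margin)
    up <- detect_upper_boundary(sp$upper_subimage,
                                min_edge_px = p$min_edge_px,
                                erode_radius = p$erode_radius,
                                sharpen_sigma = p$sharpen_sigma,
                                sharpen_amount = p$sharpen_amount,
                                median_size = p$median_size)
    lo <- detect_lower_boundary(sp$lower_subimage,
                                min_obj_px = p$min_obj_px,
                                entropy_radius = p$entropy_radius,
                                peak_frac = p$peak_frac,
                                row_offset = sp$split_row)
    init <- build_initial_mask(up, lo, c(image$height_px, image$width_px))
    mask <- refine_roi_chan_vese(image, init,
                                 iterations = p$chan_vese_iterations,
                                 sd_radius = p$sd_radius,
                                 tol = p$chan_vese_tol,
                                 max_displacement_px = p$chan_vese_max_displacement)
    if (!any(mask)) empty_mask_error("refined ROI is empty")
    mg_roi(mask, upper = up, lower = lo, status = "auto")
  }, mg_error = function(e) {
    mg_roi(NULL, status = "failed",
           error = list(class = class(e)[1], message = conditionMessage(e)))
  })
  res
}

# Eyelid height (px) at a given 0-based column: distance between the fitted
# boundary curves when available, otherwise the mask's column extent.
roi_height_at <- function(roi, x) {
  if (!is.null(roi$upper) && !is.null(roi$lower)) {
    h <- eval_boundary(roi$lower, x) - eval_boundary(roi$upper, x)
    if (h <= 0) outside_roi_error("column outside the ROI span")
    return(h)
  }
  col <- roi$mask[, round(x) + 1L]
  if (!any(col)) outside_roi_error("column outside the ROI span")
  diff(range(which(col))) + 1
}
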