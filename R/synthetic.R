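## Synthetic meibography generator with full ground truth.
##
## Emulates the image properties the pipeline is sensitive to: a bright
## tarsal band bounded by a convex upper and concave lower edge, vertical
## bright glands with Gaussian cross-profiles, contiguous dropout spans,
## saturated specular reflections, a smooth illumination gradient, and
## additive noise. It does not attempt photorealistic tissue texture.

#' Synthetic meibography parameters
#'
#' Defaults target the reference acquisition geometry: a 1360 x 1024 px
#' frame with glands about 20 px wide spanning nearly the full height of
#' the tarsal band.
#'
#' @param width_px,height_px frame size in px.
#' @param n_glands number of glands across the band.
#' @param gland_width_px mean gland width (px).
#' @param gland_width_sd SD of per-gland width (px).
#' @param gland_length_fraction fraction of the local band height spanned
#'   by each gland.
#' @param dropout_fraction fraction of the ROI area converted to a
#'   contiguous dropout region (equals the target DOA / 100).
#' @param boundary_wave_amplitude sinuous lateral wobble of gland
#'   centerlines (px).
#' @param n_reflections number of saturated specular blobs.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param illumination_gradient intensity span of a smooth left-right
#'   illumination ramp.
#' @param mm_per_px pixel scale recorded in the output image.
#' @param seed integer seed fixing every random draw.
#' @return List of class `mg_synth_params`.
#' @export
synthetic_params <- function(width_px = 1360L, height_px = 1024L,
                             n_glands = 30L, gland_width_px = 20,
                             gland_width_sd = 2,
                             gland_length_fraction = 1,
                             dropout_fraction = 0,
                             boundary_wave_amplitude = 3,
                             n_reflections = 3L, noise_sd = 4,
                             illumination_gradient = 20,
                             mm_per_px = 0.02, seed = 1L) {
  p <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
            n_glands = as.integer(n_glands), gland_width_px = gland_width_px,
            gland_width_sd = gland_width_sd,
            gland_length_fraction = gland_length_fraction,
            dropout_fraction = dropout_fraction,
            boundary_wave_amplitude = boundary_wave_amplitude,
            n_reflections = as.integer(n_reflections), noise_sd = noise_sd,
            illumination_gradient = illumination_gradient,
            mm_per_px = mm_per_px, seed = as.integer(seed))
  if (p$width_px < 100L || p$height_px < 100L)
    parameter_error("frame must be at least 100 x 100 px")
  if (p$dropout_fraction < 0 || p$dropout_fraction > 1)
    parameter_error("dropout_fraction must lie in [0, 1]")
  if (p$gland_length_fraction <= 0 || p$gland_length_fraction > 1)
    parameter_error("gland_length_fraction must lie in (0, 1]")
  if (p$n_glands < 0L || p$noise_sd < 0 || p$gland_width_px <= 0)
    parameter_error("invalid synthetic parameters")
  structure(p, class = "mg_synth_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic meibography image with ground truth
#'
#' Renders the tarsal band between a convex upper and a concave lower
#' boundary curve, places near-vertical glands with Gaussian intensity
#' cross-profiles, removes glands inside a contiguous dropout span sized
#' to `dropout_fraction` of the ROI, stamps saturated reflection blobs,
#' and adds an illumination ramp plus Gaussian noise. All truth layers
#' are returned; the truth DOA satisfies the dropout-area identity
#' exactly on the truth pixel counts.
#'
#' @param params an [synthetic_params()] object.
#' @return List of class `mg_synth_sample`: `image` ([mg_image]),
#'   `truth_roi`, `truth_glands`, `truth_dropout`, `truth_reflections`
#'   (logical matrices), `truth_doa_percent`, `gland_truth` (data.frame of
#'   per-gland centers, widths and lengths), and the boundary curve
#'   functions used.
#' @export
generate_meibography <- function(params = synthetic_params()) {
  p <- params
  with_seed(p$seed, {
    w <- p$width_px; h <- p$height_px
    xs <- 0:(w - 1)
    cx <- w / 2 + stats::runif(1, -0.04, 0.04) * w
    a <- (0.30 + stats::runif(1, -0.05, 0.05)) * h / (w / 2)^2
    y0u <- (0.16 + stats::runif(1, -0.02, 0.02)) * h
    upper_fun <- function(x) y0u + a * (x - cx)^2
    b <- (0.18 + stats::runif(1, -0.04, 0.04)) * h / (w / 2)^2
    y0l <- (0.85 + stats::runif(1, -0.02, 0.02)) * h
    lower_fun <- function(x) y0l - b * (x - cx)^2
    yu <- upper_fun(xs); yl <- lower_fun(xs)
    ys <- 0:(h - 1)
    roi <- outer(ys, yu, ">=") & outer(ys, yl, "<")

    # contiguous dropout span (temporal side), sized on ROI column areas
    col_area <- colSums(roi)
    target <- p$dropout_fraction * sum(roi)
    dropout <- matrix(FALSE, h, w)
    if (target > 0) {
      cum <- cumsum(rev(col_area))       # grow from the right edge
      ncut <- which(cum >= target)[1]
      if (is.na(ncut)) ncut <- w
      dropout[, (w - ncut + 1L):w] <- roi[, (w - ncut + 1L):w]
    }

    # glands on the non-dropout part of the band
    glands <- matrix(FALSE, h, w)
    base <- matrix(0, h, w)
    spacing <- w / max(p$n_glands, 1)
    centers <- (seq_len(p$n_glands) - 0.5) * spacing
    # jitter kept small so intergland gaps stay narrower than a gland
    # width, as they are anatomically
    centers <- centers + stats::runif(p$n_glands, -0.1, 0.1) * spacing
    widths <- pmax(4, stats::rnorm(p$n_glands, p$gland_width_px, p$gland_width_sd))
    lenfr <- pmin(1, pmax(0.1, p$gland_length_fraction +
                            stats::rnorm(p$n_glands, 0, 0.01)))
    phase <- stats::runif(p$n_glands, 0, 2 * pi)
    gl_rows <- vector("list", p$n_glands)
    for (g in seq_len(p$n_glands)) {
      xc <- centers[g]
      yu_g <- upper_fun(xc); yl_g <- lower_fun(xc)
      hh <- yl_g - yu_g
      top <- yu_g + (1 - lenfr[g]) / 2 * hh
      bot <- yl_g - (1 - lenfr[g]) / 2 * hh
      rows <- which(ys >= top & ys < bot)
      if (length(rows) == 0) next
      xline <- xc + p$boundary_wave_amplitude *
        sin(2 * pi * ys[rows] / 300 + phase[g])
      cols_lo <- pmax(1L, floor(xline - widths[g] / 2) + 1L)
      cols_hi <- pmin(w, ceiling(xline + widths[g] / 2) + 1L)
      sigma <- widths[g] / 2.5
      for (k in seq_along(rows)) {
        cc <- cols_lo[k]:cols_hi[k]
        dx <- (cc - 1) - xline[k]
        base[rows[k], cc] <- pmax(base[rows[k], cc],
                                  75 * exp(-dx^2 / (2 * sigma^2)))
        inside <- cc[abs(dx) <= widths[g] / 2]
        glands[rows[k], inside] <- TRUE
      }
      gl_rows[[g]] <- data.frame(
        gland = g, center_x = xc, width_px = widths[g],
        length_px = length(rows), top_y = min(ys[rows]), bottom_y = max(ys[rows])
      )
    }
    glands <- glands & roi & !dropout
    base[dropout] <- 0
    base[!roi] <- 0
    gland_truth <- do.call(rbind, gl_rows)
    if (!is.null(gland_truth)) {
      # drop glands fully erased by the dropout span
      kept <- vapply(seq_len(nrow(gland_truth)), function(i) {
        any(glands[, max(1, floor(gland_truth$center_x[i] - 1)):
                     min(w, ceiling(gland_truth$center_x[i] + 3))])
      }, logical(1))
      gland_truth$in_dropout <- !kept
    }

    # intensity model
    img <- matrix(20, h, w)
    img[roi] <- 90
    img <- img + base
    # specular reflections: saturated blobs on glandular tissue
    refl <- matrix(FALSE, h, w)
    placed <- 0L; tries <- 0L
    while (placed < p$n_reflections && tries < 200L) {
      tries <- tries + 1L
      gx <- sample.int(w, 1); gy <- sample.int(h, 1)
      if (!roi[gy, gx] || dropout[gy, gx]) next
      r <- stats::runif(1, 5, 9)
      yy <- pmax(1, floor(gy - r)):pmin(h, ceiling(gy + r))
      xx <- pmax(1, floor(gx - r)):pmin(w, ceiling(gx + r))
      d2 <- outer((yy - gy)^2, (xx - gx)^2, "+")
      blob <- d2 <= r^2
      sub <- refl[yy, xx]; sub[blob] <- TRUE
      refl[yy, xx] <- sub
      placed <- placed + 1L
    }
    refl <- refl & roi & !dropout
    img[refl] <- 255
    ramp <- matrix(rep(seq(-0.5, 0.5, length.out = w) * p$illumination_gradient,
                       each = h), h, w)
    img <- img + ramp + stats::rnorm(h * w, 0, p$noise_sd)
    img[refl] <- 255                        # keep reflections saturated
    img <- round(pmin(pmax(img, 0), 255))

    n_roi <- sum(roi)
    n_r <- sum(refl)
    n_gl <- n_roi - sum(dropout) - n_r      # truth gland region: ROI minus
                                            # dropout minus reflections
    structure(
      list(
        image = mg_image(img, mm_per_px = p$mm_per_px,
                         source_id = sprintf("synthetic-seed%d", p$seed)),
        truth_roi = roi,
        truth_glands = glands,
        truth_dropout = dropout,
        truth_reflections = refl,
        truth_doa_percent = 100 * (n_roi - n_gl - n_r) / n_roi,
        gland_truth = gland_truth,
        upper_fun = upper_fun, lower_fun = lower_fun,
        params = p
      ),
      class = "mg_synth_sample"
    )
  })
}

#' Generate a parametric gland shape
#'
#' An elongated vertical shape whose boundary radius about the center is
#' the moment ellipse radius modulated by `1 + wave_amplitude *
#' sin(n_lobes * theta)`; zero amplitude yields a smooth regular gland.
#'
#' @param length_px,width_px vertical and horizontal extent (px),
#'   `length_px >= width_px > 0`.
#' @param wave_amplitude boundary modulation in normalized-radius units.
#' @param n_lobes number of sinusoidal lobes.
#' @param seed optional seed (only used for reproducibility bookkeeping;
#'   the shape itself is deterministic).
#' @return Logical matrix just enclosing the shape.
#' @export
generate_gland_shape <- function(length_px, width_px, wave_amplitude = 0,
                                 n_lobes = 6L, seed = NULL) {
  if (width_px <= 0 || length_px < width_px)
    parameter_error("need length_px >= width_px > 0")
  if (wave_amplitude < 0 || wave_amplitude >= 1)
    parameter_error("wave_amplitude must lie in [0, 1)")
  a <- length_px / 2; b <- width_px / 2
  pad <- ceiling(a * (1 + wave_amplitude)) + 2L
  n <- 2L * pad + 1L
  cy <- cx <- pad + 1L
  yy <- matrix(rep(seq_len(n) - cy, n), n)          # vertical offset
  xx <- t(matrix(rep(seq_len(n) - cx, n), n))       # horizontal offset
  theta <- atan2(-yy, xx)
  # ellipse with major axis vertical: r0(theta) = ab / sqrt((b sin)^2+(a cos)^2)
  r0 <- a * b / sqrt((b * sin(theta))^2 + (a * cos(theta))^2)
  rmod <- r0 * (1 + wave_amplitude * sin(n_lobes * theta))
  sqrt(yy^2 + xx^2) <= rmod
}

#' Build the reference envelope from synthetic regular glands
#'
#' Samples `n` regular (zero-waviness) gland shapes with natural size
#' variation, computes their normalized radial profiles and aggregates
#' them into a per-angle mean +/- SD envelope.
#'
#' @param n number of reference glands (default 200).
#' @param seed RNG seed.
#' @return An `mg_envelope`.
#' @export
build_reference_envelope <- function(n = 200L, seed = 1905L) {
  if (n < 2L)
    insufficient_reference_error("need at least 2 reference glands")
  with_seed(seed, {
    profiles <- vector("list", n)
    for (i in seq_len(n)) {
      len <- stats::rnorm(1, 120, 15)
      wid <- stats::rnorm(1, 24, 3)
      len <- max(len, 40); wid <- min(max(wid, 10), len)
      shape <- generate_gland_shape(len, wid, 0)
      profiles[[i]] <- radial_profile(shape)
    }
    build_envelope(profiles)
  })
}
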