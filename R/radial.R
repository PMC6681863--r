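## Polar boundary profiles and the gland-irregularity score.
##
## A gland's shape is described by tracing its boundary, converting the
## boundary coordinates to polar form about the mass center, sampling the
## radius at 1-degree steps, and normalizing by the maximum radius. The
## irregularity of a profile is the area (trapezoidal integration over
## degrees) by which it leaves a reference envelope built from a
## population of regular glands (per-angle mean +/- 1 SD).

#' Normalized polar boundary profile of a gland
#'
#' The 8-connected outer boundary of the shape is traced, each boundary
#' pixel is expressed in polar coordinates about the mass center, radii
#' are sampled at 1-degree bins (0..359) and divided by the maximum
#' radius. When a ray crosses the boundary more than once (non-star-shaped
#' gland) the outermost crossing is kept and a `non_star_shaped_warning`
#' is emitted. Empty bins are filled by circular linear interpolation.
#'
#' @param shape logical matrix, a single filled gland shape.
#' @return List of class `mg_radial_profile` with `angles_deg` (0..359),
#'   `radii_norm` (max = 1) and `mass_center` (0-based x, y).
#' @export
radial_profile <- function(shape) {
  pix <- which(shape, arr.ind = TRUE)
  if (nrow(pix) < 3L)
    degenerate_object_error("shape too small for a radial profile")
  mc <- c(x = mean(pix[, 2]) - 1, y = mean(pix[, 1]) - 1)
  # outer boundary: foreground pixels with at least one 4-neighbour outside
  inner <- shape &
    shift_mat(shape, 1L, 0L) & shift_mat(shape, -1L, 0L) &
    shift_mat(shape, 0L, 1L) & shift_mat(shape, 0L, -1L)
  # border pixels of the matrix are boundary if foreground
  inner[c(1L, nrow(shape)), ] <- FALSE
  inner[, c(1L, ncol(shape))] <- FALSE
  bnd <- which(shape & !inner, arr.ind = TRUE)
  dx <- bnd[, 2] - 1 - mc["x"]
  dy <- bnd[, 1] - 1 - mc["y"]
  r <- sqrt(dx * dx + dy * dy)
  if (any(r <= 0))
    degenerate_object_error("mass center lies on the boundary")
  ang <- (atan2(-dy, dx) * 180 / pi) %% 360   # y up, degrees 0..360
  bin <- floor(ang) %% 360L + 1L
  rmax <- rep(NA_real_, 360)
  rmin <- rep(NA_real_, 360)
  for (k in seq_along(r)) {
    b <- bin[k]
    if (is.na(rmax[b]) || r[k] > rmax[b]) rmax[b] <- r[k]
    if (is.na(rmin[b]) || r[k] < rmin[b]) rmin[b] <- r[k]
  }
  filled <- !is.na(rmax)
  # non-star shapes: within-bin radius spread well beyond discretization
  spread <- (rmax[filled] - rmin[filled]) / pmax(rmax[filled], 1e-9)
  if (any(spread > 0.25 & (rmax[filled] - rmin[filled]) > 3))
    mg_warn("non_star_shaped_warning",
            "boundary crossed more than once along some rays; using the outermost crossing")
  radii <- rmax
  if (!all(filled)) {
    # circular linear interpolation over empty bins
    idx <- which(filled)
    th <- c(idx, idx[1] + 360)
    vals <- c(radii[idx], radii[idx[1]])
    miss <- which(!filled)
    for (m in miss) {
      mm <- if (m < idx[1]) m + 360 else m
      radii[m] <- stats::approx(th, vals, xout = mm)$y
    }
  }
  radii <- radii / max(radii)
  structure(
    list(angles_deg = 0:359, radii_norm = radii,
         mass_center = unname(mc)),
    class = "mg_radial_profile"
  )
}

#' Reference irregularity envelope
#'
#' Per-angle sample mean and standard deviation of a set of normalized
#' radial profiles; `mean - sd` and `mean + sd` are the limits within
#' which a regular gland's profile is expected to stay.
#'
#' @param profiles list of `mg_radial_profile` objects (or plain numeric
#'   vectors of 360 radii), at least 2.
#' @return List of class `mg_envelope` with `mean_profile`, `sd_profile`,
#'   `n_reference`.
#' @export
build_envelope <- function(profiles) {
  if (length(profiles) < 2L)
    insufficient_reference_error("need at least 2 reference profiles")
  mat <- vapply(profiles, function(p) {
    if (inherits(p, "mg_radial_profile")) p$radii_norm else as.numeric(p)
  }, numeric(360))
  structure(
    list(mean_profile = rowMeans(mat),
         sd_profile = apply(mat, 1L, stats::sd),
         n_reference = length(profiles)),
    class = "mg_envelope"
  )
}

#' Irregularity score of a radial profile
#'
#' Trapezoidal integral over angle (in degrees) of the excess of the
#' profile above `mean + sd` plus its deficit below `mean - sd`; zero
#' where the profile stays inside the envelope. Because profiles are
#' normalized, the score is invariant to gland size and position.
#'
#' @param profile an `mg_radial_profile` or numeric vector of 360 radii.
#' @param envelope an `mg_envelope`.
#' @return Nonnegative score (normalized-radius x degrees).
#' @export
irregularity_score <- function(profile, envelope) {
  p <- if (inherits(profile, "mg_radial_profile")) profile$radii_norm
       else as.numeric(profile)
  if (length(p) != length(envelope$mean_profile))
    parameter_error("profile and envelope sampled on different angles")
  upper <- envelope$mean_profile + envelope$sd_profile
  lower <- envelope$mean_profile - envelope$sd_profile
  excess <- pmax(p - upper, 0) + pmax(lower - p, 0)
  pracma::trapz(0:(length(p) - 1), excess)
}

#' Write / read an envelope as a 360-row CSV (angle, mean, sd)
#' @param envelope an `mg_envelope`.
#' @param path CSV path.
#' @export
write_envelope_csv <- function(envelope, path) {
  utils::write.csv(
    data.frame(angle_deg = 0:359,
               mean = envelope$mean_profile,
               sd = envelope$sd_profile),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  if (!file.exists(path))
    file_not_found_error(sprintf("no such file: %s", path))
  d <- utils::read.csv(path)
  structure(
    list(mean_profile = d$mean, sd_profile = d$sd,
         n_reference = NA_integer_),
    class = "mg_envelope"
  )
}

#' Bundled reference envelope
#'
#' The envelope shipped with the package is built from 200 synthetic
#' regular glands produced by [generate_gland_shape()] with zero boundary
#' waviness and natural size variation. It is a synthetic stand-in for a
#' clinically derived envelope: rebuild one from your own segmented
#' regular glands with [build_envelope()] for clinical use.
#'
#' @return An `mg_envelope`.
#' @export
mg_reference_envelope <- function() {
  path <- system.file("extdata", "reference_envelope_synthetic.csv",
                      package = "meibographr")
  if (nzchar(path) && file.exists(path)) return(read_envelope_csv(path))
  build_reference_envelope(200L, seed = 1905L)
}
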