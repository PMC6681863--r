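## Eyelid-level report: DOA plus per-gland and mean morphometrics,
## shaped like the summary table of a clinical read-out (DOA %, number of
## glands, irregularity, relative length %, length mm, width mm).

#' Summarize one eyelid
#'
#' Runs the dropout-area estimation ([estimate_gland_region()],
#' [detect_reflections()], [compute_doa()]) and the per-gland
#' morphometrics (moment-ellipse length/width, relative length, radial
#' profile and irregularity) and aggregates eyelid-level means. The
#' eyelid irregularity is the irregularity score of the per-angle mean
#' profile across all glands; per-gland scores are also reported.
#'
#' @param labelmap an `mg_labelmap` (after fragmentation).
#' @param roi an `mg_roi`.
#' @param gray original grayscale intensities (0-255).
#' @param envelope an `mg_envelope` (default: the bundled synthetic
#'   reference envelope).
#' @param mm_per_px pixel scale.
#' @param config an [mg_config] (disk radius, reflection threshold,
#'   gland-region method).
#' @return List of class `mg_report`; `per_gland` is a data.frame with
#'   one row per gland.
#' @export
eyelid_summary <- function(labelmap, roi, gray,
                           envelope = mg_reference_envelope(),
                           mm_per_px = 0.02, config = mg_config()) {
  mp <- config$morphometrics
  gmask <- labelmap$labels > 0L
  gl <- estimate_gland_region(gmask, roi, disk_radius = mp$disk_radius,
                              method = mp$gland_region_method)
  rf <- detect_reflections(gray, roi, threshold = mp$reflection_threshold)
  # the dropout accounting uses the same measurement domain as the gland
  # detector: the rim band next to the ROI boundary, where foreground is
  # suppressed during segmentation, is excluded from all three counts
  rim <- config$segmentation$rim_px
  dom <- if (rim > 0L) box_sum((!roi$mask) * 1, rim, rim) == 0 else roi$mask
  # reflections inside the estimated gland region are already counted there
  n_px_roi <- sum(dom)
  n_px_gl <- sum(gl$mask & dom)
  n_px_r <- sum(rf$mask & dom & !gl$mask)
  doa <- compute_doa(n_px_roi, n_px_gl, n_px_r)
  n <- labelmap$n_glands
  per <- NULL
  profiles <- list()
  if (n > 0L) {
    rows <- vector("list", n)
    px_all <- which(labelmap$labels > 0L, arr.ind = TRUE)
    by_label <- split.data.frame(px_all, labelmap$labels[px_all])
    for (l in seq_len(n)) {
      pix <- as.matrix(by_label[[as.character(l)]])
      # work on the padded bounding box, not the full frame
      r0 <- min(pix[, 1]) - 2L; c0 <- min(pix[, 2]) - 2L
      obj <- matrix(FALSE, max(pix[, 1]) - r0 + 3L, max(pix[, 2]) - c0 + 3L)
      obj[cbind(pix[, 1] - r0 + 1L, pix[, 2] - c0 + 1L)] <- TRUE
      met <- gland_ellipse_metrics(pix, mm_per_px)
      rel <- tryCatch(relative_length(met$length_px, roi, met$centroid_x),
                      mg_error = function(e) NA_real_)
      if (!is.na(rel) && rel > 100)
        mg_warn("relative_length_warning",
                sprintf("gland %d relative length %.1f%% exceeds 100%%", l, rel))
      prof <- tryCatch(radial_profile(obj),
                       degenerate_object_error = function(e) NULL)
      irr <- if (!is.null(prof)) irregularity_score(prof, envelope) else NA_real_
      if (!is.null(prof)) profiles[[length(profiles) + 1L]] <- prof
      rows[[l]] <- data.frame(
        gland = l,
        length_px = met$length_px, width_px = met$width_px,
        length_mm = met$length_mm, width_mm = met$width_mm,
        orientation_deg = met$orientation_deg,
        relative_length_percent = rel,
        irregularity = irr
      )
    }
    per <- do.call(rbind, rows)
  }
  eyelid_irr <- if (length(profiles) > 0L) {
    mean_prof <- rowMeans(vapply(profiles, `[[`, numeric(360), "radii_norm"))
    irregularity_score(mean_prof, envelope)
  } else NA_real_
  structure(
    list(
      doa = doa,
      n_glands = n,
      mean_length_mm = if (n > 0L) mean(per$length_mm) else NA_real_,
      mean_width_mm = if (n > 0L) mean(per$width_mm) else NA_real_,
      mean_relative_length = if (n > 0L) mean(per$relative_length_percent, na.rm = TRUE) else NA_real_,
      eyelid_irregularity = eyelid_irr,
      per_gland = per
    ),
    class = "mg_report"
  )
}

#' @export
print.mg_report <- function(x, ...) {
  cat("<mg_report>\n")
  cat(sprintf("  DOA:             %.2f %%\n", x$doa$doa_percent))
  cat(sprintf("  glands:          %d\n", x$n_glands))
  cat(sprintf("  irregularity:    %s\n", fmt_or_na(x$eyelid_irregularity)))
  cat(sprintf("  rel. length:     %s %%\n", fmt_or_na(x$mean_relative_length)))
  cat(sprintf("  mean length:     %s mm\n", fmt_or_na(x$mean_length_mm)))
  cat(sprintf("  mean width:      %s mm\n", fmt_or_na(x$mean_width_mm)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.2f", v)

#' Flatten a report to a one-row data.frame (summary-table shape)
#'
#' @param report an `mg_report` (or the result of [analyze_image()]).
#' @return One-row data.frame with columns `doa_percent`, `n_glands`,
#'   `irregularity`, `relative_length_percent`, `length_mm`, `width_mm`.
#' @export
report_row <- function(report) {
  data.frame(
    doa_percent = if (is.null(report$doa)) NA_real_ else report$doa$doa_percent,
    n_glands = if (is.null(report$n_glands)) NA_integer_ else report$n_glands,
    irregularity = null_na(report$eyelid_irregularity),
    relative_length_percent = null_na(report$mean_relative_length),
    length_mm = null_na(report$mean_length_mm),
    width_mm = null_na(report$mean_width_mm)
  )
}

null_na <- function(v) if (is.null(v)) NA_real_ else v

#' Serialize a report as JSON
#' @param report an `mg_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$doa <- unclass(out$doa)
  # drop the heavy in-memory intermediates; JSON carries the numbers
  out$roi <- NULL
  out$labelmap <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
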