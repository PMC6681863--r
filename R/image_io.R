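#' Meibography image container
#'
#' Wraps a grayscale intensity grid together with the pixel-scale metadata
#' used downstream. Intensities are stored on the native 8-bit scale
#' (0--255) with rows = y (increasing downward) and columns = x.
#'
#' @param pixels numeric matrix of intensities in [0, 255], rows = y.
#' @param mm_per_px physical size of one pixel in millimetres.
#' @param source_id text label identifying the acquisition.
#' @return An object of class `mg_image`.
#' @export
mg_image <- function(pixels, mm_per_px = 0.02, source_id = "unknown") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0)
    parameter_error("pixels must be a nonempty numeric matrix")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    parameter_error("intensities must be finite and within [0, 255]")
  if (!is.numeric(mm_per_px) || mm_per_px <= 0)
    parameter_error("mm_per_px must be a positive real")
  structure(
    list(
      pixels = pixels,
      width_px = ncol(pixels),
      height_px = nrow(pixels),
      mm_per_px = mm_per_px,
      source_id = source_id
    ),
    class = "mg_image"
  )
}

#' @export
print.mg_image <- function(x, ...) {
  cat(sprintf(
    "<mg_image> %s: %d x %d px, %.4f mm/px, intensity [%.0f, %.0f]\n",
    x$source_id, x$width_px, x$height_px, x$mm_per_px,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# ITU-R 601 luma weights; acquisition-device frames are near-monochrome so
# the exact choice is immaterial, but it must be fixed.
rgb_to_gray <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

#' Read a meibography image from disk
#'
#' Reads an 8-bit grayscale or 24-bit RGB raster (PNG or uncompressed BMP)
#' and converts it to a grayscale [mg_image]. RGB input is collapsed with
#' ITU-R 601 luma weights.
#'
#' @param path file path; format is chosen by extension (`.png`, `.bmp`).
#' @inheritParams mg_image
#' @return An [mg_image].
#' @export
read_meibography <- function(path, mm_per_px = 0.02) {
  if (!file.exists(path))
    file_not_found_error(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = read_png_gray(path),
    bmp = read_bmp_gray(path),
    unsupported_format_error(sprintf("unsupported image format: .%s", ext))
  )
  mg_image(px, mm_per_px = mm_per_px, source_id = basename(path))
}

read_png_gray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) {
    px <- a * 255
  } else {
    nc <- dim(a)[3]
    if (nc >= 3L) {
      px <- rgb_to_gray(a[, , 1], a[, , 2], a[, , 3]) * 255
    } else {
      px <- a[, , 1] * 255
    }
  }
  round(px)
}

# Minimal reader for uncompressed BMP rasters (BITMAPINFOHEADER, 8-bit
# palette or 24-bit BGR, bottom-up or top-down rows). No installed package
# reads BMP, and the format's uncompressed layout is simple enough to parse
# directly.
read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    unsupported_format_error("not a BMP file")
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * c(1, 256, 65536, 16777216))
  data_offset <- u32(11)
  header_size <- u32(15)
  if (header_size < 40)
    unsupported_format_error("unsupported BMP header")
  width <- u32(19)
  height_raw <- u32(23)
  top_down <- height_raw > 2^31
  height <- if (top_down) 2^32 - height_raw else height_raw
  bpp <- u16(29)
  compression <- u32(31)
  if (compression != 0)
    unsupported_format_error("compressed BMP not supported")
  if (!bpp %in% c(8, 24))
    unsupported_format_error(sprintf("unsupported BMP bit depth: %d", bpp))
  if (bpp == 8) {
    n_colors <- u32(47)
    if (n_colors == 0) n_colors <- 256
    pal_at <- 14 + header_size
    pal <- matrix(as.integer(raw[pal_at + seq_len(4 * n_colors)]),
                  ncol = 4, byrow = TRUE)  # B, G, R, reserved
    gray_lut <- rgb_to_gray(pal[, 3], pal[, 2], pal[, 1])
  }
  bytes_pp <- bpp / 8
  stride <- 4 * ceiling(width * bytes_pp / 4)
  px <- matrix(0, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    row_start <- data_offset + (r - 1) * stride
    vals <- as.integer(raw[row_start + seq_len(width * bytes_pp)])
    line <- if (bpp == 8) {
      gray_lut[vals + 1L]
    } else {
      v <- matrix(vals, nrow = 3)  # B, G, R
      rgb_to_gray(v[3, ], v[2, ], v[1, ])
    }
    y <- if (top_down) r else height - r + 1
    px[y, ] <- line
  }
  round(px)
}

# Write a grayscale matrix (0-255) as 8-bit PNG.
write_gray_png <- function(px, path) {
  png::writePNG(pmin(pmax(px, 0), 255) / 255, path)
  invisible(path)
}

#' Write a gland label map as a PNG
#'
#' Label values are stored directly as gray levels (0 = background), so
#' the map reads back losslessly with any viewer; eyelids carry far fewer
#' than 255 glands.
#'
#' @param labels integer label matrix (0 = background).
#' @param path output path.
#' @export
write_labelmap_png <- function(labels, path) {
  if (max(labels) > 255L)
    parameter_error("more than 255 labels cannot be stored in one channel")
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read a manual ROI polygon
#'
#' Plain-text file with one `x,y` vertex per line (0-based pixel
#' coordinates).
#'
#' @param path file path.
#' @return Two-column numeric matrix of vertices.
#' @export
read_roi_polygon <- function(path) {
  if (!file.exists(path))
    file_not_found_error(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  xy <- do.call(rbind, lapply(strsplit(lines, ","), function(p) {
    if (length(p) != 2) unsupported_format_error("polygon lines must be 'x,y'")
    as.numeric(p)
  }))
  if (nrow(xy) < 3 || any(!is.finite(xy)))
    parameter_error("polygon needs at least 3 finite vertices")
  colnames(xy) <- c("x", "y")
  xy
}

# Rasterize a polygon (0-based vertex coordinates) onto a height x width
# grid by even-odd ray casting at pixel centers.
rasterize_polygon <- function(vertices, height, width) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  mask <- matrix(FALSE, height, width)
  xs <- seq_len(width) - 1L
  for (row in seq_len(height)) {
    y <- row - 1
    crossings <- rep(0L, width)
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > y) != (vy[j] > y)) {
        xint <- vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
        crossings <- crossings + (xs < xint)
      }
      j <- i
    }
    mask[row, ] <- crossings %% 2L == 1L
  }
  mask
}
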