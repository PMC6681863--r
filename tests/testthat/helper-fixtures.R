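# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures are stored.

# A filled axis-aligned ellipse mask (semi-axes in px, vertical major axis
# when a >= b).
make_ellipse_mask <- function(a_vert, b_horiz, pad = 4L) {
  h <- 2L * ceiling(a_vert) + 2L * pad + 1L
  w <- 2L * ceiling(b_horiz) + 2L * pad + 1L
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(rep(seq_len(h) - cy, w), h)
  xx <- matrix(rep(seq_len(w) - cx, each = h), h)
  (yy / a_vert)^2 + (xx / b_horiz)^2 <= 1
}

# Rotate a mask by angle (degrees) about its center using inverse nearest-
# neighbour mapping (no external dependencies, adequate for moment tests).
rotate_mask <- function(mask, angle_deg) {
  h <- nrow(mask); w <- ncol(mask)
  n <- max(h, w) + 2L * ceiling(max(h, w) / 4)
  out <- matrix(FALSE, n, n)
  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  my <- (h + 1) / 2; mx <- (w + 1) / 2
  th <- angle_deg * pi / 180
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dy <- i - cy; dx <- j - cx
    # inverse rotation back into source coordinates (y down, so the sign
    # convention makes positive angles counter-clockwise on screen)
    sy <- my + (cos(th) * dy + sin(th) * dx)
    sx <- mx + (-sin(th) * dy + cos(th) * dx)
    iy <- round(sy); ix <- round(sx)
    if (iy >= 1 && iy <= h && ix >= 1 && ix <= w && mask[iy, ix])
      out[i, j] <- TRUE
  }
  out
}

# A vertical bar mask of given height x width inside a padded frame.
make_bar_mask <- function(height, width, frame_h = height + 20L,
                          frame_w = width + 20L, top = 11L, left = 11L) {
  m <- matrix(FALSE, frame_h, frame_w)
  m[top:(top + height - 1L), left:(left + width - 1L)] <- TRUE
  m
}

# Two vertical bars joined by a thin bridge at the top (fork fixture).
# bar_h x bar_w bars, gap columns between them, bridge_h rows on top.
make_fork_mask <- function(bar_h = 100L, bar_w = 20L, gap = 14L,
                           bridge_h = 10L) {
  w <- 2L * bar_w + gap + 20L
  h <- bar_h + 20L
  m <- matrix(FALSE, h, w)
  x1 <- 11L; x2 <- x1 + bar_w + gap
  m[11L:(10L + bar_h), x1:(x1 + bar_w - 1L)] <- TRUE
  m[11L:(10L + bar_h), x2:(x2 + bar_w - 1L)] <- TRUE
  m[11L:(10L + bridge_h), (x1 + bar_w):(x2 - 1L)] <- TRUE  # bridge
  m
}

# A small synthetic eyelid-like ROI object for segmentation tests: flat
# band with bright vertical stripes. Returns image (0-255), roi, stripes.
make_stripe_scene <- function(n_stripes = 10L, h = 400L, w = 620L,
                              stripe_w = 20L, intensity = 170,
                              background = 90) {
  img <- matrix(20, h, w)
  roi <- matrix(FALSE, h, w)
  roi[31:(h - 30L), 21:(w - 20L)] <- TRUE
  img[roi] <- background
  stripes <- matrix(FALSE, h, w)
  centers <- round(seq(50, w - 50, length.out = n_stripes))
  for (cx in centers) {
    cols <- (cx - stripe_w %/% 2):(cx + stripe_w %/% 2)
    rows <- 41:(h - 40L)
    stripes[rows, cols] <- TRUE
  }
  stripes <- stripes & roi
  img[stripes] <- intensity
  list(image = img, roi_mask = roi, stripes = stripes, centers = centers)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Minimal 8-bit palette BMP writer (bottom-up, uncompressed) used to test
# the package's BMP reader against known pixel content.
write_test_bmp8 <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  stride <- 4L * ceiling(w / 4)
  u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  con <- file(path, "wb"); on.exit(close(con))
  offset <- 14L + 40L + 256L * 4L
  writeBin(charToRaw("BM"), con)
  u32(offset + stride * h); u16(0); u16(0); u32(offset)
  u32(40); u32(w); u32(h); u16(1); u16(8); u32(0); u32(stride * h)
  u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  writeBin(pal, con)
  for (r in seq(h, 1)) {
    row <- as.raw(round(px[r, ]))
    writeBin(c(row, raw(stride - w)), con)
  }
  invisible(path)
}

roi_from_mask <- function(mask) {
  r <- meibographr:::mg_roi(mask, status = "manual")
  r
}
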