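test_that("DOA formula reproduces direct arithmetic and guards its domain", {
  expect_equal(compute_doa(100000, 100000, 0)$doa_percent, 0)
  expect_equal(compute_doa(100000, 0, 0)$doa_percent, 100)
  expect_equal(compute_doa(200000, 150000, 10000)$doa_percent, 20)
  expect_error(compute_doa(0, 0, 0), class = "invalid_counts_error")
  expect_error(compute_doa(100, 80, 30), class = "invalid_counts_error")
})

test_that("DOA is bounded and monotone in gland pixels removed", {
  set.seed(3)
  for (i in 1:20) {
    n_roi <- sample(1000:100000, 1)
    n_gl <- sample(0:n_roi, 1)
    n_r <- sample(0:(n_roi - n_gl), 1)
    d <- compute_doa(n_roi, n_gl, n_r)$doa_percent
    expect_gte(d, 0); expect_lte(d, 100)
    if (n_gl > 0) {
      d2 <- compute_doa(n_roi, n_gl - 1, n_r)$doa_percent
      expect_gte(d2, d)
    }
  }
})

test_that("reflection detection uses a strict intensity threshold inside the ROI", {
  g <- matrix(100, 50, 50)
  roi <- roi_from_mask(matrix(TRUE, 50, 50))
  expect_identical(detect_reflections(g, roi)$n_px_r, 0L)
  g2 <- matrix(255, 50, 50)
  expect_identical(detect_reflections(g2, roi)$n_px_r, roi$area_px)
  g3 <- matrix(100, 50, 50); g3[10, 10] <- 201; g3[20, 20] <- 200
  r3 <- detect_reflections(g3, roi)
  expect_identical(r3$n_px_r, 1L)         # 200 itself is not flagged
  expect_true(r3$mask[10, 10]); expect_false(r3$mask[20, 20])
})

# brute-force closing oracle on small masks: dilate then erode with an
# explicit disk offset list
brute_close <- function(mask, r) {
  offs <- which(EBImage::makeBrush(2L * r + 1L, "disc") > 0,
                arr.ind = TRUE) - (r + 1L)
  h <- nrow(mask); w <- ncol(mask)
  cy <- (r + 1L):(r + h); cx <- (r + 1L):(r + w)
  dil <- matrix(FALSE, h + 2L * r, w + 2L * r)
  for (k in seq_len(nrow(offs))) {
    sub <- dil[cy + offs[k, 1], cx + offs[k, 2]]
    dil[cy + offs[k, 1], cx + offs[k, 2]] <- sub | mask
  }
  ero <- matrix(TRUE, h, w)
  for (k in seq_len(nrow(offs)))
    ero <- ero & dil[cy + offs[k, 1], cx + offs[k, 2]]
  ero
}

test_that("gland-region closing fills narrow intergland gaps only", {
  h <- 200L; w <- 200L
  roi <- roi_from_mask(matrix(TRUE, h, w))
  # two 20-px bars with a 10-px gap: gap is intergland, gets filled
  m <- matrix(FALSE, h, w)
  m[60:140, 60:79] <- TRUE; m[60:140, 90:109] <- TRUE
  est <- estimate_gland_region(m, roi, disk_radius = 20L)
  expect_true(all(est$mask[80:120, 80:89]))         # gap interior filled
  oracle <- brute_close(m, 20L)
  expect_gte(sum(est$mask & oracle) / sum(est$mask | oracle), 0.98)
  # two bars 100 px apart: deep gap interior stays open (dropout)
  m2 <- matrix(FALSE, 160L, 260L)
  m2[20:140, 21:40] <- TRUE; m2[20:140, 141:160] <- TRUE
  roi2 <- roi_from_mask(matrix(TRUE, 160L, 260L))
  est2 <- estimate_gland_region(m2, roi2, disk_radius = 20L)
  expect_false(any(est2$mask[60:100, 75:105]))
  # empty mask
  expect_identical(estimate_gland_region(matrix(FALSE, 10, 10),
                                         roi_from_mask(matrix(TRUE, 10, 10)))$n_px_gl, 0L)
})

test_that("closing is extensive and idempotent", {
  set.seed(9)
  h <- 100L; w <- 140L
  roi <- roi_from_mask(matrix(TRUE, h, w))
  m <- matrix(FALSE, h, w)
  for (k in 1:4) {
    x0 <- sample(10:(w - 30), 1)
    m[sample(10:40, 1):sample(60:90, 1), x0:(x0 + sample(5:20, 1))] <- TRUE
  }
  c1 <- estimate_gland_region(m, roi, 10L)$mask
  expect_true(all(c1[m]))                          # extensive
  c2 <- estimate_gland_region(c1, roi, 10L)$mask
  expect_identical(c2, c1)                         # idempotent
})

test_that("moment-ellipse metrics reproduce known shapes", {
  # filled ellipse, semi-axes 50 (vertical) and 10: the moment ellipse of
  # an ellipse is itself
  e <- make_ellipse_mask(50, 10)
  m <- gland_ellipse_metrics(e, mm_per_px = 0.02)
  expect_equal(m$length_px, 100, tolerance = 0.02)
  expect_equal(m$width_px, 20, tolerance = 0.02)
  expect_equal(m$orientation_deg, 90, tolerance = 1)
  expect_equal(m$length_mm, m$length_px * 0.02)
  # filled 20 x 100 rectangle: uniform second moment L^2/12 equates to an
  # ellipse axis 2L/sqrt(3) = 115.47
  r <- make_bar_mask(100L, 20L)
  mr <- gland_ellipse_metrics(r)
  expect_equal(mr$length_px, 2 * 100 / sqrt(3), tolerance = 0.01)
  expect_equal(mr$width_px, 2 * 20 / sqrt(3), tolerance = 0.01)
  expect_error(gland_ellipse_metrics(matrix(FALSE, 5, 5)),
               class = "degenerate_object_error")
})

test_that("moment-ellipse metrics are rotation-equivariant within tolerance", {
  e <- make_ellipse_mask(50, 10)
  m0 <- gland_ellipse_metrics(e)
  for (ang in c(30, 45, 75)) {
    mr <- gland_ellipse_metrics(rotate_mask(e, ang))
    expect_equal(mr$length_px, m0$length_px, tolerance = 0.02)
    expect_equal(mr$width_px, m0$width_px, tolerance = 0.02)
    dtheta <- abs(((mr$orientation_deg - (90 + ang)) + 90) %% 180 - 90)
    expect_lt(dtheta, 2)
  }
  # translation invariance
  sh <- matrix(FALSE, nrow(e) + 40, ncol(e) + 60)
  sh[31:(30 + nrow(e)), 51:(50 + ncol(e))] <- e
  ms <- gland_ellipse_metrics(sh)
  expect_equal(ms$length_px, m0$length_px)
  expect_equal(ms$width_px, m0$width_px)
})

test_that("moment ellipse agrees with an independent moment implementation", {
  # EBImage computes the same major axis from normalized second moments
  e <- make_ellipse_mask(37, 12)
  f <- EBImage::computeFeatures.moment(EBImage::bwlabel(e * 1))
  m <- gland_ellipse_metrics(e)
  expect_equal(m$length_px, unname(f[1, "m.majoraxis"]), tolerance = 0.01)
})

test_that("relative length uses the local eyelid height", {
  mask <- matrix(FALSE, 200, 100); mask[51:150, ] <- TRUE
  roi <- roi_from_mask(mask)
  expect_equal(relative_length(100, roi, 50), 100, tolerance = 0.01)
  expect_equal(relative_length(50, roi, 50), 50, tolerance = 0.01)
  expect_error(relative_length(50, roi, 150), class = "outside_roi_error")
})
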