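# Rasterize a step scene: bright below a curve, dark above (or the
# reverse), over a given canvas.
rasterize_step <- function(h, w, curve_fun, bright_below = TRUE,
                           lo = 20, hi = 160) {
  ys <- matrix(rep(0:(h - 1), w), h)
  yc <- matrix(rep(curve_fun(0:(w - 1)), each = h), h)
  below <- ys >= yc
  img <- matrix(lo, h, w)
  img[below == bright_below] <- hi
  img
}

test_that("eyelid split partitions the image at the bright band", {
  s <- generate_meibography(synthetic_params(seed = 11, height_px = 512L,
                                             width_px = 680L))
  sp <- split_eyelid_image(s$image)
  expect_gt(sp$split_row, 0L)
  expect_lt(sp$split_row, 511L)
  # split falls inside the band
  yu <- s$upper_fun(340); yl <- s$lower_fun(340)
  expect_gt(sp$split_row, yu - 40)
  expect_lt(sp$split_row, yl + 40)
  # partition property: recombination restores the input exactly
  expect_identical(rbind(sp$upper_subimage, sp$lower_subimage),
                   s$image$pixels)
  expect_error(split_eyelid_image(mg_image(matrix(50, 200, 200))),
               class = "flat_image_error")
})

test_that("upper-boundary detector recovers a known convex quadratic", {
  h <- 520L; w <- 1360L
  f <- function(x) 5e-4 * x^2 - 0.3 * x + 400
  img <- rasterize_step(h, w, f)
  up <- detect_upper_boundary(img)
  expect_identical(up$kind, "quadratic")
  expect_equal(up$coefficients[3], 5e-4, tolerance = 0.2)
  # fitted curve tracks the rasterized edge closely in the interior
  xs <- seq(100, w - 100, by = 50)
  expect_lt(sqrt(mean((eval_boundary(up, xs) - f(xs))^2)), 8)
  expect_error(detect_upper_boundary(matrix(100, 520, 400)),
               class = "no_boundary_error")
  expect_error(detect_upper_boundary(img[1:30, ]),
               class = "parameter_error")
})

test_that("among candidate edges the smallest positive curvature wins", {
  h <- 700L; w <- 1360L
  f_pos <- function(x) 0.001 * (x - 680)^2 * 0.5 + 150  # a = 5e-4
  img <- matrix(20, h, w)
  ys <- matrix(rep(0:(h - 1), w), h)
  y1 <- matrix(rep(f_pos(0:(w - 1)), each = h), h)
  # bright band between the convex top edge and a concave bottom edge
  f_neg <- function(x) 650 - 0.002 * (x - 680)^2 * 0.5
  y2 <- matrix(rep(f_neg(0:(w - 1)), each = h), h)
  img[ys >= y1 & ys < y2] <- 160
  up <- detect_upper_boundary(img)
  # the concave bottom edge fits with a negative quadratic term and must
  # not be chosen
  expect_gt(up$coefficients[3], 0)
  expect_equal(up$coefficients[3], 5e-4, tolerance = 0.25)
  xs <- seq(200, 1100, by = 100)
  expect_lt(max(abs(eval_boundary(up, xs) - f_pos(xs))), 16)
})

test_that("lower-boundary detector fits a known concave edge", {
  h <- 520L; w <- 1360L
  set.seed(4)
  f <- function(x) 300 - 2.2e-4 * (x - 680)^2
  # textured above the edge, dark below: entropy drops across the edge
  img <- matrix(20, h, w) + matrix(rnorm(h * w, 0, 2), h, w)
  ys <- matrix(rep(0:(h - 1), w), h)
  yc <- matrix(rep(f(0:(w - 1)), each = h), h)
  tex <- matrix(sample(c(60, 160), h * w, replace = TRUE), h, w)
  img[ys < yc] <- tex[ys < yc]
  lo <- detect_lower_boundary(img)
  expect_identical(lo$kind, "chebyshev4")
  expect_lte(lo$coefficients[5], 0)   # concavity constraint
  xs <- seq(100, w - 100, by = 50)
  expect_lt(sqrt(mean((eval_boundary(lo, xs) - f(xs))^2)), 8)
  # degenerate flat edge: constant fit
  img2 <- matrix(20, 520, 1360)
  img2[1:300, ] <- tex[1:300, ]
  lo2 <- detect_lower_boundary(img2)
  expect_equal(eval_boundary(lo2, c(100, 680, 1200)), rep(299, 3),
               tolerance = 6)
  expect_error(detect_lower_boundary(matrix(50, 300, 1360)),
               class = "no_boundary_error")
})

test_that("lower-boundary constrained fit never returns positive quartic term", {
  set.seed(21)
  for (i in 1:10) {
    x <- 0:800
    y <- 250 + runif(1, -0.1, 0.1) * (x - 400) +
      runif(1, -4e-4, 4e-4) * (x - 400)^2 + rnorm(length(x), 0, 3)
    fit <- meibographr:::fit_chebyshev4(x, y)
    expect_lte(fit$coefficients[5], 0)
  }
})

test_that("initial mask fills strictly between the curves (half-open rows)", {
  up <- meibographr:::mg_boundary("quadratic", c(100, 0, 0), c(0, 9), 0)
  lo <- meibographr:::mg_boundary("quadratic", c(200, 0, 0), c(0, 9), 0)
  m <- build_initial_mask(up, lo, c(300L, 10L))
  expect_identical(sum(m), 1000L)       # 100 rows x 10 columns
  expect_true(all(which(rowSums(m) > 0) %in% 101:200))
  # crossing curves contribute nothing where upper >= lower
  up2 <- meibographr:::mg_boundary("quadratic", c(150, 1, 0), c(0, 99), 0)
  lo2 <- meibographr:::mg_boundary("quadratic", c(200, 0, 0), c(0, 99), 0)
  m2 <- build_initial_mask(up2, lo2, c(400L, 100L))
  expect_identical(sum(m2[, 60:100]), 0L)    # upper(x) >= 200 for x >= 50
  expect_error(build_initial_mask(lo, up, c(300L, 10L)),
               class = "empty_mask_error")
})

test_that("Chan-Vese refinement recovers a textured band from a dilated seed", {
  set.seed(31)
  h <- 300L; w <- 300L
  truth <- matrix(FALSE, h, w); truth[101:200, 31:270] <- TRUE
  px <- matrix(30, h, w) + matrix(rnorm(h * w, 0, 2), h, w)
  px[truth] <- 120 + rnorm(sum(truth), 0, 35)   # high-variance band
  px <- pmin(pmax(px, 0), 255)
  img <- mg_image(round(px))
  seed_mask <- EBImage::dilate(truth * 1, EBImage::makeBrush(21, "disc")) > 0.5
  ref <- refine_roi_chan_vese(img, seed_mask, iterations = 60L)
  expect_gte(jaccard(ref, truth), 0.95)
  # zero iterations: seed returned untouched
  expect_identical(refine_roi_chan_vese(img, seed_mask, iterations = 0L),
                   seed_mask)
  expect_error(refine_roi_chan_vese(img, matrix(FALSE, h, w)),
               class = "empty_mask_error")
})

test_that("select_roi reports status rather than raising", {
  s <- generate_meibography(synthetic_params(seed = 17))
  roi <- select_roi(s$image)
  expect_identical(roi$status, "auto")
  expect_gt(roi$area_px, 0L)
  # single 8-connected component entirely inside the frame
  lab <- meibographr:::label8(roi$mask)
  expect_identical(max(lab), 1L)
  # uniform image: failure is encoded, not raised
  flat <- mg_image(matrix(77, 600, 800))
  r2 <- select_roi(flat)
  expect_identical(r2$status, "failed")
  expect_identical(r2$error$class, "flat_image_error")
  # manual polygon: rasterized area
  poly <- rbind(c(10, 10), c(89, 10), c(89, 59), c(10, 59))
  r3 <- select_roi(mg_image(matrix(0, 100, 100)), manual_polygon = poly)
  expect_identical(r3$status, "manual")
  expect_equal(r3$area_px, 80 * 50, tolerance = 0.05)
})

test_that("automatic ROI recovers the generator truth band", {
  ok <- 0L
  for (sd_ in 41:44) {
    s <- generate_meibography(synthetic_params(seed = sd_,
                                               dropout_fraction = 0.2))
    roi <- select_roi(s$image)
    if (roi$status == "auto" &&
        jaccard(roi$mask, s$truth_roi) >= 0.85) ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})
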