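test_that("difference-of-Gaussians band-pass removes DC and obeys linearity", {
  const <- matrix(7, 60, 60)
  expect_lt(max(abs(bandpass_dog(const))), 1e-8)
  # single unit impulse: response equals the kernel difference centred there
  imp <- matrix(0, 81, 81); imp[41, 41] <- 1
  resp <- bandpass_dog(imp, 2, 8)
  g <- function(s) {
    k <- outer(dnorm(-40:40, sd = s), dnorm(-40:40, sd = s))
    k / sum(k)
  }
  # absolute comparison: kernel truncation radii differ slightly
  expect_lt(max(abs(resp[31:51, 31:51] - (g(2) - g(8))[31:51, 31:51])),
            2e-4)
  expect_error(bandpass_dog(const, 30, 2), class = "parameter_error")
})

test_that("band-pass prefers gland-scale stripes over coarse bands", {
  w <- 400L; h <- 200L
  fine <- matrix(rep(sin(2 * pi * (0:(w - 1)) / 40), each = h), h, w)
  coarse <- matrix(rep(sin(2 * pi * (0:(w - 1)) / 400), each = h), h, w)
  a_fine <- stats::sd(bandpass_dog(fine)[, 100:300])
  a_coarse <- stats::sd(bandpass_dog(coarse)[, 100:300])
  expect_gt(a_fine, a_coarse)
})

test_that("stripe scene segmentation recovers exactly the stripe count", {
  sc <- make_stripe_scene(n_stripes = 10L)
  bp <- bandpass_dog(sc$image)
  m <- segment_glands(bp, roi_from_mask(sc$roi_mask))
  lm <- label_glands(m)
  expect_identical(lm$n_glands, 10L)
  expect_true(all(m[sc$roi_mask == FALSE] == FALSE))   # inside ROI only
  expect_error(segment_glands(bp, roi_from_mask(sc$roi_mask & FALSE)),
               class = "empty_roi_error")
})

test_that("orientation and size filters drop non-gland objects", {
  # a horizontal bright bar is removed by the orientation rule
  img <- matrix(20, 300, 500)
  roi <- matrix(FALSE, 300, 500); roi[21:280, 21:480] <- TRUE
  img[roi] <- 90
  img[140:160, 60:420] <- 170     # horizontal bar, orientation ~ 0
  m <- segment_glands(bandpass_dog(img), roi_from_mask(roi))
  expect_identical(label_glands(m)$n_glands, 0L)
  # a small blob (< 800 px) is removed by the size floor
  img2 <- matrix(20, 300, 500); img2[roi] <- 90
  img2[140:160, 240:260] <- 170   # ~ 440 px
  m2 <- segment_glands(bandpass_dog(img2), roi_from_mask(roi))
  expect_identical(sum(m2), 0L)
})

test_that("object orientation matches constructed angles", {
  bar_v <- make_bar_mask(100L, 5L)
  expect_equal(object_orientation(which(bar_v, arr.ind = TRUE)), 90,
               tolerance = 0.5)
  bar_h <- matrix(FALSE, 25, 120); bar_h[11:15, 11:110] <- TRUE
  expect_equal(object_orientation(which(bar_h, arr.ind = TRUE)), 0,
               tolerance = 0.5)
  # rotated elongated fixture: equivariant within discretization
  # (rotate_mask turns the on-screen shape clockwise, which moves the
  # measured angle from vertical toward 90 + ang)
  e <- make_ellipse_mask(50, 8)
  for (ang in c(20, 45, 70)) {
    got <- object_orientation(which(rotate_mask(e, ang), arr.ind = TRUE))
    expected <- (90 + ang) %% 180
    expect_lt(abs(((got - expected) + 90) %% 180 - 90), 2)
  }
  expect_error(object_orientation(cbind(1, 1)),
               class = "degenerate_object_error")
})

test_that("labels run left-to-right by centroid column", {
  m <- matrix(FALSE, 200, 400)
  m[20:180, 300:320] <- TRUE   # right bar first in raster order
  m[20:180, 100:120] <- TRUE
  lm <- label_glands(m)
  expect_identical(lm$n_glands, 2L)
  expect_true(all(lm$labels[50, 100:120] == 1L))
  expect_true(all(lm$labels[50, 300:320] == 2L))
  expect_identical(label_glands(matrix(FALSE, 10, 10))$n_glands, 0L)
  expect_identical(label_glands(make_bar_mask(50L, 10L))$n_glands, 1L)
})

test_that("fork fixtures fragment into their constituent glands", {
  fork <- make_fork_mask(bar_h = 100L, bar_w = 20L, gap = 14L, bridge_h = 10L)
  lm <- label_glands(fork)
  expect_identical(lm$n_glands, 1L)
  fr <- fragment_compound_glands(lm)
  expect_identical(fr$n_glands, 2L)
  # straight vertical bar with aspect ratio >= 3 passes through unchanged
  bar <- make_bar_mask(90L, 20L)
  fb <- fragment_compound_glands(label_glands(bar))
  expect_identical(fb$n_glands, 1L)
  expect_identical(fb$labels > 0L, bar)
  # short fork whose fragments would be squat is kept intact
  shortfork <- make_fork_mask(bar_h = 45L, bar_w = 20L, gap = 14L,
                              bridge_h = 10L)
  fs <- fragment_compound_glands(label_glands(shortfork))
  expect_identical(fs$n_glands, 1L)
})

test_that("fragmentation conserves pixels and is idempotent", {
  fixtures <- list(
    make_fork_mask(100L, 20L, 14L, 10L),
    make_fork_mask(120L, 16L, 20L, 8L),
    make_fork_mask(45L, 20L, 14L, 10L),
    make_bar_mask(90L, 20L)
  )
  # a triple fork
  tri <- matrix(FALSE, 130, 130)
  for (x0 in c(11L, 51L, 91L)) tri[11:120, x0:(x0 + 19L)] <- TRUE
  tri[11:20, 11:110] <- TRUE
  fixtures <- c(fixtures, list(tri))
  for (f in fixtures) {
    lm <- label_glands(f)
    fr1 <- fragment_compound_glands(lm)
    expect_identical(fr1$labels > 0L, lm$labels > 0L)   # conservation
    fr2 <- fragment_compound_glands(fr1)
    expect_identical(fr2$labels, fr1$labels)            # idempotence
    expect_identical(fr2$n_glands, fr1$n_glands)
  }
})

test_that("gland count is recovered across gland densities", {
  for (n in c(5L, 15L, 25L)) {
    ok <- 0L
    for (sd_ in 1:3) {
      s <- generate_meibography(synthetic_params(
        seed = 100L + sd_, n_glands = n, dropout_fraction = 0,
        width_px = 1360L, height_px = 1024L))
      roi <- roi_from_mask(s$truth_roi)   # isolate segmentation from ROI
      m <- segment_glands(bandpass_dog(s$image$pixels), roi)
      lm <- fragment_compound_glands(label_glands(m))
      if (lm$n_glands == n) ok <- ok + 1L
    }
    expect_gte(ok, 2L)
  }
})
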