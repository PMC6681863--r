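test_that("radial profile of a circle is unity at every angle", {
  d <- make_ellipse_mask(40, 40)
  p <- radial_profile(d)
  expect_equal(max(p$radii_norm), 1)
  expect_true(all(p$radii_norm > 0.95))   # discretization only
})

test_that("radial profile of a 2:1 ellipse dips to 0.5 at the minor axis", {
  e <- make_ellipse_mask(100, 50)
  p <- radial_profile(e)
  expect_equal(min(p$radii_norm), 0.5, tolerance = 0.03)
  expect_equal(max(p$radii_norm), 1)
  # minima at the horizontal directions (0 and 180 deg)
  expect_lt(p$radii_norm[1], 0.55)
  expect_lt(p$radii_norm[181], 0.55)
  expect_gt(p$radii_norm[91], 0.95)
})

test_that("a sinusoidally perturbed disk shows its lobes in the profile", {
  s <- generate_gland_shape(160, 120, wave_amplitude = 0.25, n_lobes = 6)
  p <- radial_profile(s)
  r <- p$radii_norm
  # count circular local maxima regions on a lightly smoothed profile
  k <- stats::filter(c(tail(r, 5), r, head(r, 5)), rep(1 / 5, 5))
  k <- as.numeric(k)[6:365]
  up <- k - c(tail(k, 1), head(k, -1))
  dn <- c(tail(k, -1), head(k, 1)) - k
  n_max <- sum(up > 0 & dn <= 0 & k > stats::median(k))
  expect_equal(n_max, 6, tolerance = 1)
})

test_that("envelope aggregates per-angle mean and sample SD", {
  p1 <- rep(0.8, 360); p2 <- rep(0.8, 360); p2[10] <- 0.9
  env <- build_envelope(list(p1, p2))
  expect_equal(env$mean_profile[1], 0.8)
  expect_equal(env$sd_profile[10], 0.1 / sqrt(2))   # sample SD, n - 1
  expect_equal(env$sd_profile[20], 0)
  env_same <- build_envelope(list(p1, p1, p1))
  expect_true(all(env_same$sd_profile == 0))
  expect_equal(env_same$mean_profile, p1)
  expect_error(build_envelope(list(p1)), class = "insufficient_reference_error")
})

test_that("irregularity is zero inside the envelope and integrates excursions", {
  env <- build_envelope(list(rep(0.7, 360), rep(0.9, 360)))  # mean .8, sd ~.141
  inside <- rep(0.8, 360)
  expect_equal(irregularity_score(inside, env), 0)
  # profile exceeding the upper limit by exactly 0.1 over a 90-degree arc
  upper <- env$mean_profile + env$sd_profile
  p <- env$mean_profile
  p[91:181] <- upper[91:181] + 0.1   # 90 full degrees of excess
  expect_equal(irregularity_score(p, env), 9, tolerance = 0.12)
  # mixed protrusions match a dense numeric oracle
  lower <- env$mean_profile - env$sd_profile
  q <- env$mean_profile
  q[20:60] <- upper[20:60] + 0.05
  q[200:300] <- lower[200:300] - 0.2
  oracle <- {
    ex <- pmax(q - upper, 0) + pmax(lower - q, 0)
    sum((ex[-360] + ex[-1]) / 2)    # trapezoid over unit-degree steps
  }
  expect_equal(irregularity_score(q, env), oracle, tolerance = 1e-9)
})

test_that("irregularity is scale- and translation-invariant and monotone", {
  env <- mg_reference_envelope()
  base <- generate_gland_shape(120, 24, wave_amplitude = 0.3, n_lobes = 6)
  s_small <- generate_gland_shape(60, 12, wave_amplitude = 0.3, n_lobes = 6)
  i_base <- irregularity_score(radial_profile(base), env)
  i_small <- irregularity_score(radial_profile(s_small), env)
  expect_gt(i_base, 0)
  expect_equal(i_small, i_base, tolerance = 0.25 * i_base)  # discretization
  # translation: embed in a larger frame
  big <- matrix(FALSE, nrow(base) + 50, ncol(base) + 70)
  big[26:(25 + nrow(base)), 61:(60 + ncol(base))] <- base
  expect_equal(irregularity_score(radial_profile(big), env), i_base)
  # monotone in protrusion amplitude
  scores <- vapply(c(0.1, 0.2, 0.3), function(a) {
    irregularity_score(radial_profile(
      generate_gland_shape(120, 24, wave_amplitude = a, n_lobes = 6)), env)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("regular synthetic glands score near zero against the shipped envelope", {
  env <- mg_reference_envelope()
  expect_true(all(env$mean_profile + env$sd_profile >=
                    env$mean_profile - env$sd_profile))
  set.seed(5)
  scores <- replicate(8, {
    len <- rnorm(1, 120, 10); wid <- rnorm(1, 24, 2)
    s <- generate_gland_shape(max(len, 60), min(max(wid, 14), 34), 0)
    irregularity_score(radial_profile(s), env)
  })
  expect_lt(mean(scores), 2)
})
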