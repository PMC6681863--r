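## Eyelid grading scales, multi-level Otsu class limits, and Cohen's kappa.

#' Grading scales for the dropout-area percentage
#'
#' Two presets are provided. `meiboscore_scale()` is the legacy subjective
#' scale: grade 0 iff DOA = 0, then (0, 32], (32, 65], (65, 100] for
#' grades 1-3. `objective_scale()` is the objective reclassification
#' derived by minimal-intraclass-variance clustering of automatically
#' estimated DOA values: [0, 16), [16, 32], (32, 59], (59, 100] for
#' grades 0-3.
#'
#' @param name scale label.
#' @param boundaries strictly increasing DOA percentages inside (0, 100);
#'   length 3 for a 4-grade scale.
#' @param right_closed logical per boundary: is the boundary value part of
#'   the lower grade (`x <= b`) rather than the upper?
#' @param zero_is_grade0 when TRUE, grade 0 applies only to DOA exactly 0
#'   (the legacy convention); otherwise grade 0 is the full first interval.
#' @return A list of class `mg_scale`.
#' @export
grading_scale <- function(name, boundaries, right_closed,
                          zero_is_grade0 = FALSE) {
  if (is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries <= 0) || any(boundaries >= 100))
    parameter_error("boundaries must be strictly increasing inside (0, 100)")
  if (length(right_closed) != length(boundaries))
    parameter_error("one inclusivity flag per boundary is required")
  structure(
    list(name = name, boundaries = boundaries, right_closed = right_closed,
         zero_is_grade0 = zero_is_grade0),
    class = "mg_scale"
  )
}

#' @rdname grading_scale
#' @export
meiboscore_scale <- function() {
  # grade 0 iff DOA = 0; 1: (0, 32]; 2: (32, 65]; 3: DOA > 65
  grading_scale("meiboscore", c(32, 65),
                right_closed = c(TRUE, TRUE), zero_is_grade0 = TRUE)
}

#' @rdname grading_scale
#' @export
objective_scale <- function() {
  # Grade 0: 0 <= DOA < 16; 1: 16 <= DOA <= 32; 2: 32 < DOA <= 59; 3: > 59
  grading_scale("objective", c(16, 32, 59),
                right_closed = c(FALSE, TRUE, TRUE))
}

#' @export
print.mg_scale <- function(x, ...) {
  cat(sprintf("<mg_scale> %s: boundaries %s\n", x$name,
              paste(signif(x$boundaries, 4), collapse = ", ")))
  invisible(x)
}

#' Grade a DOA percentage
#'
#' Maps DOA values to integer grades 0..k under the scale's boundary
#' conventions; the mapping is monotone nondecreasing in DOA and every
#' DOA in [0, 100] maps to exactly one grade.
#'
#' @param doa_percent numeric vector of DOA percentages in [0, 100].
#' @param scale an `mg_scale`.
#' @return Integer vector of grades.
#' @export
grade <- function(doa_percent, scale = objective_scale()) {
  if (any(doa_percent < 0 | doa_percent > 100 | !is.finite(doa_percent)))
    out_of_range_error("DOA must lie in [0, 100]")
  vapply(doa_percent, function(d) {
    g <- 0L
    for (i in seq_along(scale$boundaries)) {
      b <- scale$boundaries[i]
      above <- if (scale$right_closed[i]) d > b else d >= b
      if (above) g <- i else break
    }
    if (scale$zero_is_grade0) {
      # interval index maps to grades 1..k; exactly zero is grade 0
      g <- if (d == 0) 0L else g + 1L
    }
    as.integer(g)
  }, integer(1))
}

#' Objective class limits by multi-level Otsu clustering
#'
#' Clusters DOA percentages into `n_classes` classes minimizing the total
#' within-class variance (multi-level Otsu). Values are binned into a
#' 101-bin histogram (1 percentage-point bins, 0..100) and all threshold
#' combinations are searched exhaustively, so the result is the exact
#' minimizer on the binned values.
#'
#' @param doa_values numeric vector of DOA percentages.
#' @param n_classes number of classes (default 4, matching the legacy
#'   grading scales).
#' @return An `mg_scale` whose boundaries follow the objective-scale
#'   conventions (`[0, b1)`, `[b1, b2]`, `(b2, b3]`, ...).
#' @export
otsu_class_limits <- function(doa_values, n_classes = 4L) {
  if (any(doa_values < 0 | doa_values > 100))
    out_of_range_error("DOA values must lie in [0, 100]")
  if (length(unique(round(doa_values))) < n_classes)
    degenerate_data_error("fewer distinct (binned) values than classes")
  bins <- 0:100
  counts <- tabulate(round(doa_values) + 1L, nbins = 101L)
  # cumulative moments for O(1) within-class sum of squared deviations
  c0 <- cumsum(counts)
  c1 <- cumsum(counts * bins)
  c2 <- cumsum(counts * bins^2)
  seg_cost <- function(lo, hi) {   # bins lo..hi, 1-based indices into 0..100
    n <- c0[hi] - if (lo > 1) c0[lo - 1] else 0
    s1 <- c1[hi] - if (lo > 1) c1[lo - 1] else 0
    s2 <- c2[hi] - if (lo > 1) c2[lo - 1] else 0
    ifelse(n > 0, s2 - s1^2 / pmax(n, 1), 0)
  }
  occ <- which(counts > 0)
  lo_bin <- min(occ); hi_bin <- max(occ)
  cand <- lo_bin:(hi_bin - 1L)      # cut after this bin
  combs <- utils::combn(cand, n_classes - 1L)
  best <- Inf; best_t <- NULL
  for (j in seq_len(ncol(combs))) {
    t <- combs[, j]
    cost <- 0
    lo <- lo_bin
    for (k in seq_along(t)) { cost <- cost + seg_cost(lo, t[k]); lo <- t[k] + 1L }
    cost <- cost + seg_cost(lo, hi_bin)
    if (cost < best) { best <- cost; best_t <- t }
  }
  # threshold bin index t (1-based into 0..100) cuts after value t-1;
  # report the first value of the next class, matching the printed
  # convention of the objective scale.
  bvals <- bins[best_t + 1L]
  grading_scale("otsu-fit", bvals,
                right_closed = c(FALSE, rep(TRUE, n_classes - 2L)))
}

#' Cohen's kappa from a confusion table
#'
#' Unweighted Cohen's kappa with the conventional Landis-Koch verbal
#' category attached.
#'
#' @param confusion square matrix of agreement counts (graders as rows and
#'   columns, same category order).
#' @return List of class `mg_kappa` with `kappa`, `observed_agreement`,
#'   `expected_agreement`, `category`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0L || sum(confusion) <= 0)
    empty_table_error("confusion table is empty")
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    parameter_error("confusion table must be square with nonnegative counts")
  n <- sum(confusion)
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa_result(p_o, p_e)
}

#' Cohen's kappa from marginal totals and an agreement count
#'
#' Computes kappa directly from the two graders' marginal category counts
#' and the number of exact agreements: the chance agreement depends only
#' on the marginals, so no full confusion table is needed.
#'
#' @param row_marginals,col_marginals category counts per grader (same
#'   order, equal totals).
#' @param n_agree number of exact agreements.
#' @return An `mg_kappa`.
#' @export
kappa_from_marginals <- function(row_marginals, col_marginals, n_agree) {
  n <- sum(row_marginals)
  if (n != sum(col_marginals))
    parameter_error("marginal totals differ between graders")
  if (n_agree < 0 || n_agree > n)
    parameter_error("agreement count outside [0, N]")
  p_o <- n_agree / n
  p_e <- sum(row_marginals * col_marginals) / n^2
  kappa_result(p_o, p_e)
}

kappa_result <- function(p_o, p_e) {
  k <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  structure(
    list(kappa = k, observed_agreement = p_o, expected_agreement = p_e,
         category = landis_koch(k)),
    class = "mg_kappa"
  )
}

#' @export
print.mg_kappa <- function(x, ...) {
  cat(sprintf("<mg_kappa> kappa = %.3f (%s); p_o = %.3f, p_e = %.3f\n",
              x$kappa, x$category, x$observed_agreement,
              x$expected_agreement))
  invisible(x)
}

# Conventional Landis-Koch verbal bands.
landis_koch <- function(kappa) {
  if (kappa <= 0) "poor"
  else if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}
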