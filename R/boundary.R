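## Boundary-curve fits for the eyelid edges.
##
## The upper boundary of the everted eyelid is convex and is modelled as a
## second-degree polynomial in x with a positive quadratic coefficient; the
## lower boundary is concave and is modelled as a degree-4 Chebyshev series
## (first kind, x rescaled to [-1, 1]) with the degree-4 coefficient
## constrained to be <= 0. Curves map 0-based column -> 0-based row.

mg_boundary <- function(kind, coefficients, domain, rms_fit_error) {
  structure(
    list(kind = kind, coefficients = coefficients,
         domain = domain, rms_fit_error = rms_fit_error),
    class = "mg_boundary"
  )
}

#' @export
print.mg_boundary <- function(x, ...) {
  cat(sprintf("<mg_boundary> %s over x in [%g, %g], rms %.2f px\n",
              x$kind, x$domain[1], x$domain[2], x$rms_fit_error))
  invisible(x)
}

chebyshev_basis <- function(u) {
  cbind(T0 = rep(1, length(u)), T1 = u, T2 = 2 * u^2 - 1,
        T3 = 4 * u^3 - 3 * u, T4 = 8 * u^4 - 8 * u^2 + 1)
}

#' Evaluate a fitted boundary curve
#'
#' @param curve an `mg_boundary`.
#' @param x 0-based column positions.
#' @return 0-based (real-valued) row coordinates.
#' @export
eval_boundary <- function(curve, x) {
  if (curve$kind == "quadratic") {
    cf <- curve$coefficients
    cf[1] + cf[2] * x + cf[3] * x^2
  } else {
    d <- curve$domain
    u <- if (d[2] > d[1]) 2 * (x - d[1]) / (d[2] - d[1]) - 1 else x * 0
    drop(chebyshev_basis(u) %*% curve$coefficients)
  }
}

# Least-squares quadratic fit y = c0 + c1 x + c2 x^2 (0-based coords).
fit_quadratic <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  cf <- unname(fit$coefficients)
  mg_boundary("quadratic", cf, range(x), sqrt(mean(fit$residuals^2)))
}

# Degree-4 Chebyshev least squares with the degree-4 coefficient
# constrained <= 0. A single bound constraint: if the unconstrained
# solution violates it, the optimum lies on the boundary c4 = 0 (KKT),
# so refit with the degree-4 term dropped.
fit_chebyshev4 <- function(x, y, domain = range(x)) {
  d <- domain
  u <- if (d[2] > d[1]) 2 * (x - d[1]) / (d[2] - d[1]) - 1 else x * 0
  B <- chebyshev_basis(u)
  fit <- stats::lm.fit(B, y)
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  if (cf[5] > 0) {
    fit <- stats::lm.fit(B[, 1:4, drop = FALSE], y)
    cf <- c(unname(fit$coefficients), 0)
    cf[is.na(cf)] <- 0
  }
  mg_boundary("chebyshev4", cf, d, sqrt(mean(fit$residuals^2)))
}

# Robust lower-envelope variant. The traced per-column bottom can only be
# contaminated downward (stray entropy blobs hang BELOW the true edge and
# merge into the component), so the true edge is the lower envelope of the
# bottom sequence: iteratively discard points sitting far above the
# current fit and refit, keeping the original domain.
fit_chebyshev4_robust <- function(x, y, n_rounds = 5L) {
  domain <- range(x)
  fit <- fit_chebyshev4(x, y, domain)
  for (k in seq_len(n_rounds)) {
    res <- y - eval_boundary(fit, x)
    q <- stats::quantile(res, c(0.25, 0.75), names = FALSE)
    cut <- q[2] + 1.5 * max(q[2] - q[1], 3)
    keep <- res <= cut
    if (all(keep) || sum(keep) < 10L) break
    x <- x[keep]; y <- y[keep]
    fit <- fit_chebyshev4(x, y, domain)
  }
  fit
}
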