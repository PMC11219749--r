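# FEP convergence gate: the run is accepted only when the recorded
# chemical-potential standard deviations vary smoothly with composition,
# judged by the R^2 of a least-squares polynomial-spline fit.

#' Convergence gate on chemical-potential uncertainties
#'
#' Fits `sigma_mu` against composition with a least-squares cubic
#' B-spline using a fixed knot budget (default `max(4, floor(n/10))`
#' interior knots, uniformly spaced over the data range) and computes
#' `R^2 = 1 - SS_res/SS_tot`.  The gate passes when `R^2` meets the
#' threshold: converged FEP uncertainties follow a smooth trend in
#' composition, while unconverged runs scatter.  A constant sigma array
#' (`SS_tot = 0`) is perfectly smooth and passes with `R^2 = 1` by
#' convention.
#'
#' @param chi Compositions (at least 8 points).
#' @param sigma_mu Non-negative uncertainties, same length.
#' @param threshold Acceptance threshold on `R^2` (default 0.99).
#' @param knots Interior knot budget; default `max(4, floor(n/10))`.
#'   Uniform interior knots nest when `(k2+1)` is a multiple of
#'   `(k1+1)`, making `R^2` non-decreasing across such budgets.
#' @param degree Spline degree (default 3).
#' @return An object of class `phasemix_gate`: list with `r_squared`,
#'   `passed`, `threshold`, `knots`, `fitted`.
#' @export
sigma_gate <- function(chi, sigma_mu, threshold = 0.99, knots = NULL, degree = 3) {
  n <- length(chi)
  if (n < 8L)
    stop_validation("sigma_gate: need at least 8 points, got %d", n)
  if (length(sigma_mu) != n)
    stop_validation("sigma_gate: chi and sigma_mu lengths differ")
  if (any(!is.finite(sigma_mu)) || any(sigma_mu < 0))
    stop_validation("sigma_gate: sigma values must be finite and non-negative")
  if (is.null(knots)) knots <- max(4L, floor(n / 10))
  rng <- range(chi)
  kn <- rng[1] + (rng[2] - rng[1]) * seq_len(knots) / (knots + 1)
  basis <- splines::bs(chi, knots = kn, degree = degree,
                       Boundary.knots = rng, intercept = TRUE)
  fit <- lm.fit(basis, sigma_mu)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((sigma_mu - mean(sigma_mu))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(r_squared = r2, passed = r2 >= threshold, threshold = threshold,
         knots = knots, fitted = as.numeric(basis %*% fit$coefficients)),
    class = "phasemix_gate"
  )
}

#' @export
print.phasemix_gate <- function(x, ...) {
  cat(sprintf("sigma_mu convergence gate: R^2 = %.5f (threshold %.3f) -> %s\n",
              x$r_squared, x$threshold, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}
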