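# One-parameter Margules activity model: fitting, curvature, spinodal
# prediction and agreement factors.  This is the orthogonal check on the
# spline-detected stability limits: the model form ln(gamma_s) =
# A_s*(1-chi)^2, ln(gamma_p) = A_p*chi^2 satisfies Gibbs-Duhem for
# symmetric solutions by construction.

#' Fit one-parameter Margules constants to activity coefficients
#'
#' Weighted least squares through the origin of `ln(gamma_s)` on
#' `(1-chi)^2` and of `ln(gamma_p)` on `chi^2` (closed form).  Least
#' squares over all interior points is preferred over averaging the
#' pointwise ratios `ln(gamma)/(1-chi)^2`, which blow up near the
#' endpoints.
#'
#' @param activity A `phasemix_activity` data frame from
#'   [gamma_from_mu()], with at least 3 interior points.
#' @param weights Optional fitting weights (per point).  Default:
#'   `1/sigma^2` from the profile's recorded `ln(gamma)` uncertainties
#'   when present (and positive), else uniform.
#' @return An object of class `phasemix_margules` with elements `A_s`,
#'   `A_p`, `residuals_s`, `residuals_p`, `chi`, `method`.
#' @export
fit_margules <- function(activity, weights = NULL) {
  if (!inherits(activity, "phasemix_activity"))
    stop_validation("fit_margules: expected an activity profile")
  if (nrow(activity) < 3L)
    stop_validation("fit_margules: need at least 3 interior points, got %d", nrow(activity))
  if (any(!is.finite(activity$gamma_s)) || any(!is.finite(activity$gamma_p)) ||
      any(activity$gamma_s <= 0) || any(activity$gamma_p <= 0))
    stop_validation("fit_margules: activity coefficients must be finite and positive")
  chi <- activity$chi
  ws <- wp <- weights
  method <- "wls"
  if (is.null(weights)) {
    if (any(activity$sigma_lngamma_s > 0) && any(activity$sigma_lngamma_p > 0)) {
      fs <- pmax(activity$sigma_lngamma_s, max(activity$sigma_lngamma_s) * 1e-3)
      fp <- pmax(activity$sigma_lngamma_p, max(activity$sigma_lngamma_p) * 1e-3)
      ws <- 1 / fs^2
      wp <- 1 / fp^2
    } else {
      ws <- wp <- rep(1, length(chi))
      method <- "ols"
    }
  }
  xs <- (1 - chi)^2
  xp <- chi^2
  ys <- log(activity$gamma_s)
  yp <- log(activity$gamma_p)
  a_s <- sum(ws * xs * ys) / sum(ws * xs^2)
  a_p <- sum(wp * xp * yp) / sum(wp * xp^2)
  structure(
    list(A_s = a_s, A_p = a_p,
         residuals_s = ys - a_s * xs, residuals_p = yp - a_p * xp,
         chi = chi, method = method),
    class = "phasemix_margules"
  )
}

#' @export
print.phasemix_margules <- function(x, ...) {
  cat(sprintf("Margules one-parameter fit (%s): A_s = %.4g, A_p = %.4g\n",
              x$method, x$A_s, x$A_p))
  cat(sprintf("  rms residuals: ln(gamma_s) %.3g, ln(gamma_p) %.3g over %d points\n",
              sqrt(mean(x$residuals_s^2)), sqrt(mean(x$residuals_p^2)), length(x$chi)))
  invisible(x)
}

# Accept either a fit object or a bare list(A_s=, A_p=)
margules_constants <- function(fit) {
  if (inherits(fit, "phasemix_margules")) return(list(A_s = fit$A_s, A_p = fit$A_p))
  if (is.list(fit) && all(c("A_s", "A_p") %in% names(fit)))
    return(list(A_s = fit$A_s, A_p = fit$A_p))
  stop_validation("expected a Margules fit or a list with A_s and A_p")
}

#' Reduced free-energy curvature of the one-parameter Margules model
#'
#' `1/(chi*(1-chi)) + 6*chi*(A_s - A_p) - 4*A_s + 2*A_p`: the ideal
#' curvature plus the analytic second derivative of the excess
#' `chi*A_s*(1-chi)^2 + (1-chi)*A_p*chi^2`.  Instability requires this
#' to be negative.
#'
#' @param chi Interior mole fraction(s), `0 < chi < 1`.
#' @param fit A `phasemix_margules` fit or a `list(A_s =, A_p =)`.
#' @return Dimensionless curvature, same length as `chi`.
#' @export
margules_d2g <- function(chi, fit) {
  if (any(chi <= 0 | chi >= 1))
    stop_domain("margules_d2g: curvature is singular at chi = 0 and 1")
  a <- margules_constants(fit)
  1 / (chi * (1 - chi)) + 6 * chi * (a$A_s - a$A_p) - 4 * a$A_s + 2 * a$A_p
}

#' Spinodal compositions predicted by a Margules fit
#'
#' Roots of [margules_d2g()] in `(0, 1)`, located by dense sign-change
#' scanning and refined by bisection to `1e-10`.  Symmetric fits with
#' `A <= 2` have no spinodal (the ideal curvature `1/(chi(1-chi)) >= 4`
#' dominates).
#'
#' @param fit A `phasemix_margules` fit or a `list(A_s =, A_p =)`.
#' @return Sorted numeric vector of 0, 1 or 2 mole fractions.
#' @export
margules_spinodals <- function(fit) {
  a <- margules_constants(fit)
  f <- function(x) margules_d2g(x, a)
  scan_roots(f, 1e-6, 1 - 1e-6, n = 2e4, tol = 1e-10, merge_tol = 1e-8)
}

#' Agreement factor between a detected and a model-predicted limit
#'
#' `1 - |predicted - detected| / detected`, computed in whichever units
#' both arguments share (weight percent by default throughout the
#' package).  Equals 1 for perfect agreement and may be negative when
#' the prediction is off by more than the detected value itself.
#'
#' @param detected Detected composition (must be non-zero).
#' @param predicted Model-predicted composition.
#' @return The agreement factor (vectorized).
#' @export
agreement_factor <- function(detected, predicted) {
  if (any(detected == 0))
    stop_domain("agreement_factor: detected composition must be non-zero")
  1 - abs(predicted - detected) / detected
}
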