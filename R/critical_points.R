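# Smoothing, differentiation and critical-point detection on dg(chi).
#
# Numerical scheme: only the *excess* part of dg is fitted with a spline;
# the ideal part (including its logarithmically divergent derivatives at
# the endpoints) is differentiated analytically.  This keeps the fitted
# object smooth and bounded on [0, 1] and makes the curvature estimate
# far more stable than differencing the full dg.

#' Smooth a free-energy profile for differentiation
#'
#' Fits a spline to the excess part of `dg` and carries the ideal part
#' analytically, so first and second derivatives of the full curve are
#' available at any interior composition.
#'
#' Methods:
#' \describe{
#'   \item{`"interpolate"`}{Cubic spline interpolation of the excess
#'     (the zero-smoothing limit; Forsythe-Malcolm-Moler end conditions,
#'     which reproduce a globally cubic excess exactly).  Default when
#'     no weights or uncertainties are available: exact data should be
#'     reproduced exactly.}
#'   \item{`"penalized"`}{Penalized regression spline
#'     (thin-plate basis, third-derivative penalty, smoothing parameter
#'     by REML, weighted by `weights`).  Default when weights are
#'     present.  The penalty null space contains all quadratics, so the
#'     one-parameter Margules excess is estimated without shrinkage
#'     bias; this matters because the spinodal search differentiates the
#'     fit twice.}
#'   \item{`"gcv"`}{Classic cubic smoothing spline on the excess with
#'     generalized cross-validation ([stats::smooth.spline]).}
#' }
#'
#' @param fe A free-energy profile from [delta_g()] or
#'   [free_energy_profile()] with at least 7 grid points.
#' @param weights Optional fitting weights.  Default: `1/sigma_dg^2`
#'   when the profile carries non-zero uncertainties (with a floor of
#'   `1e-3 * max(sigma_dg)` to keep exact endpoints finite-weighted),
#'   else none.
#' @param method One of `"auto"`, `"interpolate"`, `"penalized"`,
#'   `"gcv"`.  `"auto"` picks `"penalized"` when weights are available
#'   and `"interpolate"` otherwise.
#' @param k Basis dimension for the penalized method (default 25).
#' @param sp Fixed smoothing parameter for `"penalized"`/`"gcv"`
#'   (bypasses REML/GCV selection).
#' @return An object of class `phasemix_curve`; evaluate it with
#'   [predict.phasemix_curve()].
#' @export
smooth_dg <- function(fe, weights = NULL, method = c("auto", "interpolate", "penalized", "gcv"),
                      k = 25, sp = NULL) {
  if (!inherits(fe, "phasemix_fe"))
    stop_validation("smooth_dg: expected a free-energy profile")
  method <- match.arg(method)
  chi <- fe$grid$chi
  y <- fe$dg_excess
  if (length(chi) < 7L)
    stop_validation("smooth_dg: need at least 7 grid points, got %d", length(chi))
  if (is.null(weights) && any(fe$sigma_dg > 0)) {
    floor_sd <- max(fe$sigma_dg) * 1e-3
    weights <- 1 / pmax(fe$sigma_dg, floor_sd)^2
  }
  if (method == "auto")
    method <- if (is.null(weights)) "interpolate" else "penalized"

  if (method == "interpolate") {
    f <- splinefun(chi, y, method = "fmm")
    excess_eval <- function(x, deriv = 0) f(x, deriv = deriv)
    resid <- rep(0, length(chi))
    par <- list(lambda = 0)
  } else if (method == "penalized") {
    dat <- data.frame(x = chi, y = y)
    w <- weights %||% rep(1, length(chi))
    fit <- suppressWarnings(mgcv::gam(
      y ~ s(x, k = min(k, length(chi) - 1L), bs = "tp", m = 3),
      data = dat, weights = w, method = "REML", sp = sp
    ))
    excess_eval <- function(x, deriv = 0) {
      p <- function(z) as.numeric(predict(fit, data.frame(x = z)))
      if (deriv == 0) return(p(x))
      h <- if (deriv == 1) 1e-5 else 1e-4
      if (deriv == 1) return((p(x + h) - p(x - h)) / (2 * h))
      if (deriv == 2) return((p(x + h) - 2 * p(x) + p(x - h)) / h^2)
      stop_domain("predict: deriv must be 0, 1 or 2")
    }
    resid <- y - as.numeric(predict(fit, data.frame(x = chi)))
    par <- list(sp = fit$sp, edf = sum(fit$edf))
  } else { # gcv
    args <- list(x = chi, y = y, all.knots = TRUE, cv = FALSE, keep.data = FALSE)
    if (!is.null(weights)) args$w <- weights
    if (!is.null(sp)) { args$spar <- sp; args$cv <- NA }
    fit <- do.call(smooth.spline, args)
    excess_eval <- function(x, deriv = 0) {
      if (deriv > 2) stop_domain("predict: deriv must be 0, 1 or 2")
      predict(fit, x, deriv = deriv)$y
    }
    resid <- y - predict(fit, chi)$y
    par <- list(lambda = fit$lambda, df = fit$df)
  }

  structure(
    list(method = method, excess_eval = excess_eval, grid = fe$grid,
         residuals = resid, par = par,
         range = range(chi)),
    class = "phasemix_curve"
  )
}

#' Evaluate a smoothed free-energy curve
#'
#' @param object A `phasemix_curve` from [smooth_dg()].
#' @param chi Compositions to evaluate at.  Derivatives require interior
#'   points (the ideal part diverges at the endpoints).
#' @param deriv Derivative order 0, 1 or 2.
#' @param part `"total"` (ideal + excess), `"excess"` or `"ideal"`.
#' @param ... Unused.
#' @return Numeric vector of curve values or derivatives.
#' @export
predict.phasemix_curve <- function(object, chi, deriv = 0, part = c("total", "excess", "ideal"), ...) {
  part <- match.arg(part)
  if (deriv > 0 && any(chi <= 0 | chi >= 1))
    stop_domain("predict: derivatives of dg are singular at chi = 0 and 1")
  exc <- if (part != "ideal") object$excess_eval(chi, deriv) else 0
  idl <- if (part != "excess") ideal_part_deriv(chi, deriv) else 0
  exc + idl
}

# kind initial used for labels
.kind_initial <- c(binodal = "b", spinodal = "s", mechanical = "m")

#' Locate binodal, spinodal and mechanical-mixture points
#'
#' Scans the smoothed curve on a dense interior grid and classifies
#' \itemize{
#'   \item binodal points: `dg' = 0` with `dg'' > 0` (local minima,
#'     single-phase compositions);
#'   \item spinodal points: `dg'' = 0` (inflections, the boundary of
#'     activationless phase separation);
#'   \item mechanical/chemical mixture limits: interior crossings of
#'     `dg = 0`, beyond which the mixed state is no more stable than the
#'     unmixed components.
#' }
#' Roots are bracketed by sign change and refined by bisection; roots of
#' the same kind closer than `1e-6` are merged.  Points are labelled
#' `b1/s1/m1` on the polymer-rich branch (below the interior maximum of
#' `dg`, or `chi < 0.5` when there is none) and `b2/s2/m2` on the
#' surfactant-rich branch.
#'
#' @param curve A `phasemix_curve` from [smooth_dg()].
#' @param system A [binary_system()] (for the weight-percent axis).
#' @param scan_points Number of scan points (default `1e4`).
#' @param span Interior scan interval in mole fraction; defaults to the
#'   interior data range of the fitted grid.
#' @return A data frame of class `phasemix_points` with columns `label`,
#'   `kind`, `chi`, `w_pct`, `branch`, ordered by `chi`.  Zero rows when
#'   no critical point exists (e.g. an ideal mixture has no interior
#'   `dg = 0` or `dg'' = 0`).
#' @export
find_critical_points <- function(curve, system, scan_points = 1e4, span = NULL) {
  chi_grid <- curve$grid$chi
  interior <- chi_grid[chi_grid > 0 & chi_grid < 1]
  if (is.null(span)) span <- range(interior)
  lo <- max(span[1], 1e-9); hi <- min(span[2], 1 - 1e-9)

  f0 <- function(x) predict(curve, x, deriv = 0)
  f1 <- function(x) predict(curve, x, deriv = 1)
  f2 <- function(x) predict(curve, x, deriv = 2)

  extrema  <- scan_roots(f1, lo, hi, n = scan_points, tol = 1e-8)
  binodal  <- extrema[f2(extrema) > 0]
  spinodal <- scan_roots(f2, lo, hi, n = scan_points, tol = 1e-8)
  mechanical <- scan_roots(f0, lo, hi, n = scan_points, tol = 1e-8)

  pts <- data.frame(
    kind = c(rep("binodal", length(binodal)),
             rep("spinodal", length(spinodal)),
             rep("mechanical", length(mechanical))),
    chi = c(binodal, spinodal, mechanical),
    stringsAsFactors = FALSE
  )
  if (nrow(pts) == 0L) {
    out <- data.frame(label = character(0), kind = character(0),
                      chi = numeric(0), w_pct = numeric(0), branch = character(0))
    class(out) <- c("phasemix_points", "data.frame")
    return(out)
  }

  # branch divider: interior maximum of dg (largest local max), else 0.5
  maxima <- extrema[f2(extrema) < 0]
  divider <- if (length(maxima)) maxima[which.max(f0(maxima))] else 0.5
  pts$branch <- ifelse(pts$chi <= divider, "polymer_rich", "surfactant_rich")
  pts$w_pct <- 100 * mol_to_wt(pts$chi, system)

  pts <- pts[order(pts$chi), , drop = FALSE]
  pts$label <- vapply(seq_len(nrow(pts)), function(i) {
    ini <- .kind_initial[[pts$kind[i]]]
    num <- if (pts$branch[i] == "polymer_rich") 1L else 2L
    same <- which(pts$kind == pts$kind[i] & pts$branch == pts$branch[i])
    pos <- match(i, same)
    if (pos == 1L) sprintf("%s%d", ini, num) else sprintf("%s%d.%d", ini, num, pos)
  }, character(1))
  rownames(pts) <- NULL
  out <- pts[, c("label", "kind", "chi", "w_pct", "branch")]
  class(out) <- c("phasemix_points", "data.frame")
  out
}

#' Classify the physical stability limit of a system
#'
#' The stability limit is the lowest-load critical point of kind
#' spinodal or mechanical/chemical mixture: binodal points are local
#' minima of the mixing free energy (single-phase) and never destabilize
#' the blend.  The destabilizing mechanism is the kind of that point.
#' With no spinodal or mechanical point on the scanned range the system
#' is reported fully miscible.
#'
#' @param points A `phasemix_points` data frame from
#'   [find_critical_points()].
#' @return An object of class `phasemix_report` with elements
#'   `critical_points`, `stability_limit` (one-row data frame or `NULL`),
#'   `mechanism` (`"mechanical_mixture"`, `"spinodal"` or
#'   `"fully_miscible"`), and `status`.
#' @export
classify_stability_limit <- function(points) {
  if (!inherits(points, "phasemix_points"))
    stop_validation("classify_stability_limit: expected a critical-point table")
  unstable <- points[points$kind %in% c("spinodal", "mechanical"), , drop = FALSE]
  if (nrow(unstable) == 0L) {
    rep <- list(critical_points = points, stability_limit = NULL,
                mechanism = "fully_miscible",
                status = "fully miscible on scanned range")
  } else {
    lim <- unstable[which.min(unstable$w_pct), , drop = FALSE]
    rep <- list(critical_points = points, stability_limit = lim,
                mechanism = if (lim$kind == "mechanical") "mechanical_mixture" else "spinodal",
                status = "stability limit located")
  }
  class(rep) <- "phasemix_report"
  rep
}

#' @export
print.phasemix_report <- function(x, ...) {
  cat("Stability report\n")
  if (nrow(x$critical_points)) {
    df <- x$critical_points
    df$chi <- signif(df$chi, 4)
    df$w_pct <- signif(df$w_pct, 4)
    print.data.frame(df, row.names = FALSE)
  } else {
    cat("  no critical points on scanned range\n")
  }
  if (is.null(x$stability_limit)) {
    cat("Status:", x$status, "\n")
  } else {
    cat(sprintf("Stability limit: %s at %.4g wt%% (chi = %.4g), mechanism = %s\n",
                x$stability_limit$label, x$stability_limit$w_pct,
                x$stability_limit$chi, x$mechanism))
  }
  invisible(x)
}
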