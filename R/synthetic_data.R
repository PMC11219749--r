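# Synthetic FEP-like chemical-potential profiles with known ground
# truth.  Stands in for an MD/FEP engine so every pipeline stage has
# parameter-recovery tests; it makes no claim to reproduce atomistic
# chemical potentials.

#' Ground-truth activity model for synthetic profiles
#'
#' Three families:
#' \describe{
#'   \item{`margules_one_param`}{`ln(gamma_s) = A*(1-chi)^2`,
#'     `ln(gamma_p) = A*chi^2` (symmetric; pass `A`).}
#'   \item{`margules_two_const`}{As above with distinct `A_s`, `A_p`.}
#'   \item{`flory_huggins`}{Polymer-solution model with interaction
#'     parameter `chi_fh` and molar size ratio `size_ratio >= 1`
#'     (polymer relative to surfactant); its excess is *not* of Margules
#'     form, which exercises robustness of the one-parameter validator.}
#' }
#'
#' @param family Model family name.
#' @param system A [binary_system()].
#' @param A Symmetric Margules constant (`margules_one_param`).
#' @param A_s,A_p Margules constants (`margules_two_const`).
#' @param chi_fh,size_ratio Flory-Huggins interaction parameter and size
#'   ratio (`flory_huggins`).
#' @return An object of class `phasemix_truth`.
#' @export
ground_truth_model <- function(family = c("margules_one_param", "margules_two_const", "flory_huggins"),
                               system, A = NULL, A_s = NULL, A_p = NULL,
                               chi_fh = NULL, size_ratio = NULL) {
  family <- tryCatch(match.arg(family),
                     error = function(e) stop_validation("ground_truth_model: unknown family '%s'", family[1]))
  pars <- switch(family,
    margules_one_param = {
      if (is.null(A) || !is.finite(A))
        stop_validation("margules_one_param requires a finite A")
      list(A_s = A, A_p = A)
    },
    margules_two_const = {
      if (is.null(A_s) || is.null(A_p) || !is.finite(A_s) || !is.finite(A_p))
        stop_validation("margules_two_const requires finite A_s and A_p")
      list(A_s = A_s, A_p = A_p)
    },
    flory_huggins = {
      if (is.null(chi_fh) || !is.finite(chi_fh))
        stop_validation("flory_huggins requires a finite chi_fh")
      size_ratio <- size_ratio %||%
        (system$polymer$molecular_weight / system$surfactant$molecular_weight)
      if (!is.finite(size_ratio) || size_ratio < 1)
        stop_validation("flory_huggins size_ratio must be >= 1")
      list(chi_fh = chi_fh, r = size_ratio)
    }
  )
  structure(list(family = family, pars = pars, system = system),
            class = "phasemix_truth")
}

# ln(gamma) pair of a truth model at interior chi
truth_lngamma <- function(model, chi) {
  p <- model$pars
  if (model$family %in% c("margules_one_param", "margules_two_const")) {
    list(s = p$A_s * (1 - chi)^2, p = p$A_p * chi^2)
  } else {
    r <- p$r
    u <- r - (r - 1) * chi
    phi_s <- chi / u
    phi_p <- r * (1 - chi) / u
    list(
      s = log(phi_s / chi) + (1 - 1 / r) * phi_p + p$chi_fh * phi_p^2,
      p = log(phi_p / (1 - chi)) + (1 - r) * phi_s + r * p$chi_fh * phi_s^2
    )
  }
}

# Analytic excess free energy of a truth model and derivatives 0..2
truth_excess <- function(model, chi, deriv = 0) {
  p <- model$pars
  if (model$family %in% c("margules_one_param", "margules_two_const")) {
    a_s <- p$A_s; a_p <- p$A_p
    switch(as.character(deriv),
      "0" = a_s * chi * (1 - chi)^2 + a_p * chi^2 * (1 - chi),
      "1" = a_s * (1 - chi) * (1 - 3 * chi) + a_p * chi * (2 - 3 * chi),
      "2" = 6 * chi * (a_s - a_p) - 4 * a_s + 2 * a_p
    )
  } else {
    r <- p$r; x <- p$chi_fh
    u <- r - (r - 1) * chi
    q <- chi * (1 - chi) / u
    nmr <- (1 - 2 * chi) * u + (r - 1) * chi * (1 - chi)
    switch(as.character(deriv),
      "0" = (1 - chi) * log(r) - log(u) + x * r * q,
      "1" = -log(r) + (r - 1) / u + x * r * nmr / u^2,
      "2" = (r - 1)^2 / u^2 + x * r * (-2 * u^2 + 2 * (r - 1) * nmr) / u^3
    )
  }
}

# Full reduced dg of a truth model, derivatives 0..2 (interior for >0)
truth_dg <- function(model, chi, deriv = 0) {
  ideal_part_deriv(chi, deriv) + truth_excess(model, chi, deriv)
}

#' Noise specification for synthetic profiles
#'
#' Heteroscedastic Gaussian noise emulating FEP statistics: the standard
#' deviation of each chemical potential is
#' `sigma_base * min(1 + dilute_inflation * (0.5/d - 1), cap)` in RT
#' units, where `d` is the distance of the composition to the nearest
#' endpoint.  `sigma_base` is thus the mid-grid noise level; the
#' uncertainty inflates as the annihilated species becomes dilute, up to
#' a documented cap (default 10x).
#'
#' @param sigma_base Mid-grid noise sd in RT units (>= 0; default 0.02).
#' @param dilute_inflation Inflation rate towards the endpoints
#'   (>= 0; default 1; 0 gives homoscedastic noise).
#' @param cap Maximum inflation factor (default 10).
#' @param seed Integer seed governing all randomness of the generator.
#' @return A list of class `phasemix_noise`.
#' @export
noise_spec <- function(sigma_base = 0.02, dilute_inflation = 1, cap = 10, seed = 1L) {
  if (sigma_base < 0) stop_validation("noise_spec: sigma_base must be >= 0")
  if (dilute_inflation < 0) stop_validation("noise_spec: dilute_inflation must be >= 0")
  if (cap < 1) stop_validation("noise_spec: cap must be >= 1")
  structure(list(sigma_base = sigma_base, dilute_inflation = dilute_inflation,
                 cap = cap, seed = as.integer(seed)),
            class = "phasemix_noise")
}

noise_sd <- function(noise, chi) {
  d <- pmin(chi, 1 - chi)
  d[d <= 0] <- .Machine$double.eps
  noise$sigma_base * pmin(1 + noise$dilute_inflation * (0.5 / d - 1), noise$cap)
}

#' Generate a synthetic chemical-potential profile
#'
#' Builds `mu_s = mu_s0 + RT*(ln(chi) + ln(gamma_s))` and
#' `mu_p = mu_p0 + RT*(ln(1-chi) + ln(gamma_p))` from the ground-truth
#' model, adds independent Gaussian noise with the heteroscedastic sd of
#' the [noise_spec()], and records the true noise sd in the sigma
#' columns.  `mu_s` at `chi = 0` and `mu_p` at `chi = 1` are `NA` (the
#' species is absent).  Deterministic for a fixed seed.
#'
#' @param model A [ground_truth_model()].
#' @param grid A [composition_grid()]; default 1 wt% steps over the full
#'   range of the model's system.
#' @param noise A [noise_spec()]; default `noise_spec()`.  Use
#'   `sigma_base = 0` for noiseless profiles.
#' @param mu_s0,mu_p0 Pure-phase reference potentials in kJ/mol
#'   (arbitrary offsets; only differences enter the pipeline).
#' @return A [chem_potential_profile()].
#' @export
generate_profile <- function(model, grid = NULL, noise = noise_spec(),
                             mu_s0 = -50, mu_p0 = -100) {
  if (!inherits(model, "phasemix_truth"))
    stop_validation("generate_profile: expected a ground-truth model")
  if (is.null(grid)) grid <- composition_grid(model$system, 1)
  rt <- rt_kj(model$system)
  chi <- grid$chi
  n <- length(chi)
  lg <- truth_lngamma(model, pmin(pmax(chi, 1e-300), 1 - 1e-16))
  mu_s <- mu_s0 + rt * (log(chi) + lg$s)
  mu_p <- mu_p0 + rt * (log1p(-chi) + lg$p)
  mu_s[chi == 0] <- NA_real_
  mu_p[chi == 1] <- NA_real_
  sd_s <- noise_sd(noise, chi)
  sd_p <- noise_sd(noise, chi)
  if (noise$sigma_base > 0) {
    set.seed(noise$seed)
    mu_s <- mu_s + rnorm(n, 0, sd_s) * rt
    mu_p <- mu_p + rnorm(n, 0, sd_p) * rt
  }
  chem_potential_profile(grid, mu_s, mu_p,
                         sigma_mu_s = sd_s * rt, sigma_mu_p = sd_p * rt)
}

#' Ground-truth critical points of a synthetic model
#'
#' Locates binodal, spinodal and mechanical/chemical mixture points on
#' the *analytic* reduced free energy of the model (closed-form
#' derivatives), independently of the spline pipeline: dense sign-change
#' scanning refined by bisection to `1e-10`.  Serves as the oracle for
#' recovery tests.
#'
#' @param model A [ground_truth_model()].
#' @param span Interior scan interval (default `c(1e-4, 1 - 1e-4)`).
#' @return A `phasemix_points` data frame (see
#'   [find_critical_points()]).
#' @export
ground_truth_points <- function(model, span = c(1e-4, 1 - 1e-4)) {
  f0 <- function(x) truth_dg(model, x, 0)
  f1 <- function(x) truth_dg(model, x, 1)
  f2 <- function(x) truth_dg(model, x, 2)
  lo <- span[1]; hi <- span[2]
  extrema <- scan_roots(f1, lo, hi, n = 4e5, tol = 1e-10)
  binodal <- extrema[f2(extrema) > 0]
  spinodal <- scan_roots(f2, lo, hi, n = 4e5, tol = 1e-10)
  mechanical <- scan_roots(f0, lo, hi, n = 4e5, tol = 1e-10)
  pts <- data.frame(
    kind = c(rep("binodal", length(binodal)),
             rep("spinodal", length(spinodal)),
             rep("mechanical", length(mechanical))),
    chi = c(binodal, spinodal, mechanical),
    stringsAsFactors = FALSE
  )
  sys <- model$system
  if (nrow(pts) == 0L) {
    out <- data.frame(label = character(0), kind = character(0),
                      chi = numeric(0), w_pct = numeric(0), branch = character(0))
    class(out) <- c("phasemix_points", "data.frame")
    return(out)
  }
  maxima <- extrema[f2(extrema) < 0]
  divider <- if (length(maxima)) maxima[which.max(f0(maxima))] else 0.5
  pts$branch <- ifelse(pts$chi <= divider, "polymer_rich", "surfactant_rich")
  pts$w_pct <- 100 * mol_to_wt(pts$chi, sys)
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
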