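# Chemical-potential profiles, Gibbs free energy of mixing, activity
# coefficients.  All reduced free energies are dimensionless (divided by
# RT); file I/O carries kJ/mol.

#' Chemical-potential profile on a composition grid
#'
#' Bundles the measured surfactant and polymer chemical potentials (and
#' their per-point uncertainties) on a composition grid.  Reference
#' chemical potentials default to the measured pure-phase endpoints
#' (`chi = 1` for the surfactant, `chi = 0` for the polymer); supply
#' `mu_s_ref`/`mu_p_ref` explicitly when the grid does not reach the
#' endpoints.  `mu_s` at `chi = 0` and `mu_p` at `chi = 1` may be `NA`
#' (the component is absent there).
#'
#' @param grid A [composition_grid()].
#' @param mu_s,mu_p Chemical potentials in kJ/mol, one value per grid row.
#' @param sigma_mu_s,sigma_mu_p Per-point standard deviations in kJ/mol
#'   (non-negative; scalar values are recycled; default 0).
#' @param mu_s_ref,mu_p_ref Optional explicit pure-phase reference
#'   potentials in kJ/mol.
#' @return An object of class `phasemix_profile`.
#' @export
chem_potential_profile <- function(grid, mu_s, mu_p,
                                   sigma_mu_s = 0, sigma_mu_p = 0,
                                   mu_s_ref = NULL, mu_p_ref = NULL) {
  n <- nrow(grid)
  if (length(mu_s) != n || length(mu_p) != n)
    stop_validation("chem_potential_profile: mu arrays must match grid length %d", n)
  if (length(sigma_mu_s) == 1L) sigma_mu_s <- rep(sigma_mu_s, n)
  if (length(sigma_mu_p) == 1L) sigma_mu_p <- rep(sigma_mu_p, n)
  if (length(sigma_mu_s) != n || length(sigma_mu_p) != n)
    stop_validation("chem_potential_profile: sigma arrays must match grid length %d", n)
  if (any(sigma_mu_s < 0, na.rm = TRUE) || any(sigma_mu_p < 0, na.rm = TRUE))
    stop_validation("chem_potential_profile: sigma values must be non-negative")
  structure(
    list(grid = grid, mu_s = as.numeric(mu_s), mu_p = as.numeric(mu_p),
         sigma_mu_s = as.numeric(sigma_mu_s), sigma_mu_p = as.numeric(sigma_mu_p),
         mu_s_ref = mu_s_ref, mu_p_ref = mu_p_ref),
    class = "phasemix_profile"
  )
}

# Resolve pure-phase references: explicit values win, else endpoints.
resolve_refs <- function(profile) {
  chi <- profile$grid$chi
  mu_s0 <- profile$mu_s_ref
  mu_p0 <- profile$mu_p_ref
  if (is.null(mu_s0)) {
    i <- which(chi == 1)
    if (!length(i) || is.na(profile$mu_s[i]))
      stop_config("delta_g: no chi = 1 endpoint and no explicit mu_s_ref")
    mu_s0 <- profile$mu_s[i]
  }
  if (is.null(mu_p0)) {
    i <- which(chi == 0)
    if (!length(i) || is.na(profile$mu_p[i]))
      stop_config("delta_g: no chi = 0 endpoint and no explicit mu_p_ref")
    mu_p0 <- profile$mu_p[i]
  }
  list(mu_s0 = mu_s0, mu_p0 = mu_p0)
}

#' Ideal part of the reduced free energy of mixing
#'
#' chi*ln(chi) + (1-chi)*ln(1-chi), with the 0*ln(0) = 0 limit applied at
#' the endpoints.  Everywhere non-positive, minimum -ln(2) at chi = 0.5.
#'
#' @param chi Mole fraction(s) in `[0, 1]`.
#' @return Dimensionless ideal mixing free energy, same length as `chi`.
#' @export
ideal_part <- function(chi) {
  if (any(!is.finite(chi)) || any(chi < 0 | chi > 1))
    stop_domain("ideal_part: chi must lie in [0, 1]")
  out <- numeric(length(chi))
  inner <- chi > 0 & chi < 1
  x <- chi[inner]
  out[inner] <- x * log(x) + (1 - x) * log1p(-x)
  out
}

# Analytic derivatives of the ideal part; interior chi only for deriv > 0.
ideal_part_deriv <- function(chi, deriv = 0) {
  switch(as.character(deriv),
    "0" = ideal_part(chi),
    "1" = log(chi / (1 - chi)),
    "2" = 1 / (chi * (1 - chi)),
    "3" = (2 * chi - 1) / (chi * (1 - chi))^2,
    stop_domain("ideal_part_deriv: deriv must be 0..3")
  )
}

#' Reduced molar Gibbs free energy of mixing from chemical potentials
#'
#' dg = chi*(mu_s - mu_s0)/RT + (1-chi)*(mu_p - mu_p0)/RT, with the
#' pure phases as reference states.  The ideal part is subtracted
#' analytically to give the excess part.  When the references are the
#' measured endpoint values, dg is exactly zero at both endpoints.
#'
#' @param profile A [chem_potential_profile()].
#' @param system A [binary_system()].
#' @return An object of class `phasemix_fe` (free-energy profile) with
#'   elements `grid`, `dg`, `dg_ideal`, `dg_excess` (all dimensionless)
#'   and `sigma_dg` (propagated uncertainty of `dg`, dimensionless).
#' @export
delta_g <- function(profile, system) {
  refs <- resolve_refs(profile)
  rt <- rt_kj(system)
  chi <- profile$grid$chi
  ds <- (profile$mu_s - refs$mu_s0) / rt
  dp <- (profile$mu_p - refs$mu_p0) / rt
  # 0 * (possibly NA/Inf) terms take their limit value 0 at the endpoints
  term_s <- ifelse(chi == 0, 0, chi * ds)
  term_p <- ifelse(chi == 1, 0, (1 - chi) * dp)
  if (any(!is.finite(term_s)) || any(!is.finite(term_p)))
    stop_validation("delta_g: non-finite chemical potential at an interior composition")
  dg <- term_s + term_p
  dgi <- ideal_part(chi)
  # At the endpoints dg is pinned to zero by the (noisy) reference
  # subtraction, so the propagated sigma there reflects the reference
  # uncertainty rather than claiming an exactly known point; weighting
  # the endpoints as exact destabilizes downstream smoothing.
  sigma_dg <- sqrt((chi * profile$sigma_mu_s / rt)^2 +
                   ((1 - chi) * profile$sigma_mu_p / rt)^2)
  sigma_dg[is.na(sigma_dg)] <- 0
  structure(
    list(grid = profile$grid, dg = dg, dg_ideal = dgi, dg_excess = dg - dgi,
         sigma_dg = sigma_dg),
    class = "phasemix_fe"
  )
}

#' Construct a free-energy profile directly
#'
#' Mainly for testing and synthetic work: supply `dg` on a grid and the
#' ideal/excess split is computed analytically.
#'
#' @param grid A [composition_grid()].
#' @param dg Reduced free energy of mixing (dimensionless), one per row.
#' @param sigma_dg Optional per-point uncertainty of `dg` (default 0).
#' @return A `phasemix_fe` object as from [delta_g()].
#' @export
free_energy_profile <- function(grid, dg, sigma_dg = 0) {
  n <- nrow(grid)
  if (length(dg) != n)
    stop_validation("free_energy_profile: dg must match grid length %d", n)
  if (length(sigma_dg) == 1L) sigma_dg <- rep(sigma_dg, n)
  dgi <- ideal_part(grid$chi)
  structure(
    list(grid = grid, dg = as.numeric(dg), dg_ideal = dgi,
         dg_excess = as.numeric(dg) - dgi, sigma_dg = as.numeric(sigma_dg)),
    class = "phasemix_fe"
  )
}

#' Excess part of the reduced free energy of mixing
#'
#' @param fe A `phasemix_fe` profile from [delta_g()].
#' @return Numeric vector `dg - dg_ideal`.
#' @export
excess_part <- function(fe) {
  if (!inherits(fe, "phasemix_fe"))
    stop_validation("excess_part: expected a free-energy profile")
  fe$dg_excess
}

#' Activity coefficients from chemical potentials
#'
#' gamma_s = exp((mu_s - mu_s0)/RT) / chi and
#' gamma_p = exp((mu_p - mu_p0)/RT) / (1 - chi), evaluated at interior
#' compositions only (the division by the vanishing fraction is singular
#' at the endpoints).
#'
#' @param profile A [chem_potential_profile()].
#' @param system A [binary_system()].
#' @param chi Optional subset of interior grid compositions to evaluate
#'   at; defaults to all interior grid points.
#' @return An object of class `phasemix_activity`: data frame with
#'   columns `chi`, `w_pct`, `gamma_s`, `gamma_p`, `sigma_lngamma_s`,
#'   `sigma_lngamma_p`.
#' @export
gamma_from_mu <- function(profile, system, chi = NULL) {
  refs <- resolve_refs(profile)
  rt <- rt_kj(system)
  grid_chi <- profile$grid$chi
  if (is.null(chi)) {
    keep <- grid_chi > 0 & grid_chi < 1
  } else {
    if (any(chi <= 0 | chi >= 1))
      stop_domain("gamma_from_mu: chi = 0 or 1 requested; activity coefficients divide by the component fraction, which vanishes there")
    keep <- match(chi, grid_chi)
    if (anyNA(keep))
      stop_domain("gamma_from_mu: requested chi not on the profile grid")
  }
  x <- grid_chi[keep]
  gs <- exp((profile$mu_s[keep] - refs$mu_s0) / rt) / x
  gp <- exp((profile$mu_p[keep] - refs$mu_p0) / rt) / (1 - x)
  out <- data.frame(
    chi = x,
    w_pct = 100 * mol_to_wt(x, system),
    gamma_s = gs,
    gamma_p = gp,
    sigma_lngamma_s = profile$sigma_mu_s[keep] / rt,
    sigma_lngamma_p = profile$sigma_mu_p[keep] / rt
  )
  class(out) <- c("phasemix_activity", "data.frame")
  out
}

#' Read a chemical-potential profile from CSV
#'
#' Expected comma-separated columns:
#' `w_pct, mu_s_kJmol, mu_p_kJmol, sigma_mu_s_kJmol, sigma_mu_p_kJmol`
#' (the sigma columns are optional and default to 0).  Rows must be
#' sorted by `w_pct`.
#'
#' @param path Path to the CSV file.
#' @param system A [binary_system()] used to build the mole-fraction axis.
#' @return A [chem_potential_profile()].
#' @export
read_profile_csv <- function(path, system) {
  if (!file.exists(path)) stop_validation("read_profile_csv: no such file '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("w_pct", "mu_s_kJmol", "mu_p_kJmol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("read_profile_csv: '%s' is missing column(s): %s",
                    path, paste(miss, collapse = ", "))
  if (is.unsorted(df$w_pct, strictly = TRUE))
    stop_validation("read_profile_csv: w_pct must be strictly increasing (check row order)")
  if (any(df$w_pct < 0 | df$w_pct > 100))
    stop_validation("read_profile_csv: w_pct outside [0, 100]")
  w <- df$w_pct / 100
  grid <- data.frame(w = w, w_pct = df$w_pct, chi = wt_to_mol(w, system))
  class(grid) <- c("phasemix_grid", "data.frame")
  chem_potential_profile(
    grid, df$mu_s_kJmol, df$mu_p_kJmol,
    sigma_mu_s = if ("sigma_mu_s_kJmol" %in% names(df)) df$sigma_mu_s_kJmol else 0,
    sigma_mu_p = if ("sigma_mu_p_kJmol" %in% names(df)) df$sigma_mu_p_kJmol else 0
  )
}

#' Write a chemical-potential profile to CSV
#'
#' Inverse of [read_profile_csv()]; numbers are written with full
#' precision so a fixed seed reproduces a byte-identical file.
#'
#' @param profile A [chem_potential_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(
    w_pct = profile$grid$w_pct,
    mu_s_kJmol = format(profile$mu_s, digits = 17, trim = TRUE),
    mu_p_kJmol = format(profile$mu_p, digits = 17, trim = TRUE),
    sigma_mu_s_kJmol = format(profile$sigma_mu_s, digits = 17, trim = TRUE),
    sigma_mu_p_kJmol = format(profile$sigma_mu_p, digits = 17, trim = TRUE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
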