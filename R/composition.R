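# Components, binary systems, and weight <-> mole fraction conversion.

# CODATA gas constant, kJ mol^-1 K^-1.
.R_GAS_KJ <- 8.314462618e-3

#' Define a mixture component
#'
#' @param name Component name.
#' @param molecular_weight Molecular weight of the model molecule in g/mol.
#'   Mole fractions computed by [wt_to_mol()] are per model molecule, not
#'   per repeat unit.
#' @param role Either `"surfactant"` or `"polymer"`.
#' @return An object of class `phasemix_component`.
#' @examples
#' component("Copovidone", 3818.088, "polymer")
#' @export
component <- function(name, molecular_weight, role = c("surfactant", "polymer")) {
  role <- match.arg(role)
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1L ||
      !is.finite(molecular_weight) || molecular_weight <= 0)
    stop_validation("component '%s': molecular_weight must be a positive number", name)
  structure(
    list(name = as.character(name), molecular_weight = molecular_weight, role = role),
    class = "phasemix_component"
  )
}

#' Define a binary surfactant/polymer system
#'
#' @param surfactant A [component()] with role `"surfactant"`.
#' @param polymer A [component()] with role `"polymer"`.
#' @param temperature_K Absolute temperature in kelvin.
#' @return An object of class `phasemix_system` with elements `surfactant`,
#'   `polymer`, `temperature_K`.
#' @examples
#' binary_system(
#'   component("Vitamin E TPGS", 1984.513, "surfactant"),
#'   component("Copovidone", 3818.088, "polymer"),
#'   temperature_K = 453.15
#' )
#' @export
binary_system <- function(surfactant, polymer, temperature_K = 453.15) {
  if (!inherits(surfactant, "phasemix_component") || surfactant$role != "surfactant")
    stop_validation("surfactant: expected a component with role 'surfactant'")
  if (!inherits(polymer, "phasemix_component") || polymer$role != "polymer")
    stop_validation("polymer: expected a component with role 'polymer'")
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0)
    stop_validation("temperature_K: must be a positive number")
  structure(
    list(surfactant = surfactant, polymer = polymer, temperature_K = temperature_K),
    class = "phasemix_system"
  )
}

#' @export
print.phasemix_system <- function(x, ...) {
  cat(sprintf("Binary system: %s (surfactant, M = %.3f g/mol) / %s (polymer, M = %.3f g/mol)\n",
              x$surfactant$name, x$surfactant$molecular_weight,
              x$polymer$name, x$polymer$molecular_weight))
  cat(sprintf("Temperature: %.2f K (RT = %.4f kJ/mol)\n", x$temperature_K, rt_kj(x)))
  invisible(x)
}

#' Thermal energy RT of a system, in kJ/mol
#'
#' @param system A [binary_system()].
#' @return RT in kJ/mol, using the CODATA gas constant.
#' @export
rt_kj <- function(system) .R_GAS_KJ * system$temperature_K

#' Vitamin E TPGS / Copovidone example system
#'
#' Convenience constructor for the Vitamin E TPGS (surfactant) with
#' Copovidone (polymer) placebo system at the hot-melt-extrusion relevant
#' temperature of 180 degrees C (453.15 K), using model-structure
#' molecular weights of 1984.513 and 3818.088 g/mol.
#'
#' @return A [binary_system()].
#' @export
vie_system <- function() {
  binary_system(
    component("Vitamin E TPGS", 1984.513, "surfactant"),
    component("Copovidone", 3818.088, "polymer"),
    temperature_K = 453.15
  )
}

#' Tween 80 / Copovidone example system
#'
#' As [vie_system()], with Tween 80 (Polysorbate 80) as the surfactant
#' (model molecular weight 1309.654 g/mol).
#'
#' @return A [binary_system()].
#' @export
t80_system <- function() {
  binary_system(
    component("Tween 80", 1309.654, "surfactant"),
    component("Copovidone", 3818.088, "polymer"),
    temperature_K = 453.15
  )
}

#' Convert surfactant weight fraction to mole fraction
#'
#' Simple two-component mixing of molecular weights:
#' chi = (w/Ms) / (w/Ms + (1-w)/Mp), per model molecule.
#'
#' @param w Surfactant weight fraction(s) in `[0, 1]`.
#' @param system A [binary_system()].
#' @return Surfactant mole fraction(s), same length as `w`.
#' @examples
#' wt_to_mol(0.5, vie_system())
#' @export
wt_to_mol <- function(w, system) {
  if (any(!is.finite(w)) || any(w < 0 | w > 1))
    stop_domain("wt_to_mol: weight fraction must lie in [0, 1]")
  ms <- system$surfactant$molecular_weight
  mp <- system$polymer$molecular_weight
  (w / ms) / (w / ms + (1 - w) / mp)
}

#' Convert surfactant mole fraction to weight fraction
#'
#' Exact inverse of [wt_to_mol()]: w = chi*Ms / (chi*Ms + (1-chi)*Mp).
#'
#' @param chi Surfactant mole fraction(s) in `[0, 1]`.
#' @param system A [binary_system()].
#' @return Surfactant weight fraction(s).
#' @export
mol_to_wt <- function(chi, system) {
  if (any(!is.finite(chi)) || any(chi < 0 | chi > 1))
    stop_domain("mol_to_wt: mole fraction must lie in [0, 1]")
  ms <- system$surfactant$molecular_weight
  mp <- system$polymer$molecular_weight
  chi * ms / (chi * ms + (1 - chi) * mp)
}

#' Build a composition grid over the full load range
#'
#' Grid from 0 to 100 wt% surfactant inclusive.  The default 1 wt% step
#' gives 101 points; 100 is always included even when the step does not
#' divide it.
#'
#' @param system A [binary_system()] (supplies molecular weights for the
#'   mole fraction axis).
#' @param step_wt_pct Grid step in weight percent, in `(0, 50]`.
#' @return A data frame of class `phasemix_grid` with columns `w`
#'   (weight fraction), `w_pct` and `chi` (mole fraction), strictly
#'   increasing.
#' @examples
#' g <- composition_grid(vie_system())
#' nrow(g)  # 101
#' @export
composition_grid <- function(system, step_wt_pct = 1) {
  if (!is.numeric(step_wt_pct) || length(step_wt_pct) != 1L ||
      !is.finite(step_wt_pct) || step_wt_pct <= 0 || step_wt_pct > 50)
    stop_domain("composition_grid: step_wt_pct must lie in (0, 50]")
  w_pct <- unique(c(seq(0, 100, by = step_wt_pct), 100))
  w <- w_pct / 100
  out <- data.frame(w = w, w_pct = w_pct, chi = wt_to_mol(w, system))
  class(out) <- c("phasemix_grid", "data.frame")
  out
}
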