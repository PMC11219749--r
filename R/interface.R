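# Pipeline driver: configuration -> profile -> convergence gate -> dg ->
# critical points -> activity coefficients -> Margules cross-validation
# -> stability report (JSON + TSV + log).

REPORT_SCHEMA_VERSION <- "1.0"

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A configuration list for [run_analysis()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("read_run_config: no such file '%s'", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

# Build a binary_system from the config's system block, naming offending
# fields in validation errors.
config_system <- function(cfg) {
  sysc <- cfg$system
  if (is.null(sysc)) stop_config("config: missing 'system' block")
  comp <- function(block, role, field) {
    if (is.null(block)) stop_config("config: missing 'system.%s'", field)
    if (is.null(block$molecular_weight))
      stop_config("config: missing 'system.%s.molecular_weight'", field)
    component(block$name %||% field, block$molecular_weight, role)
  }
  tc <- sysc$temperature_C
  if (is.null(tc)) stop_config("config: missing 'system.temperature_C'")
  binary_system(comp(sysc$surfactant, "surfactant", "surfactant"),
                comp(sysc$polymer, "polymer", "polymer"),
                temperature_K = tc + 273.15)
}

config_model <- function(cfg, system) {
  syn <- cfg$synthetic
  ground_truth_model(
    family = syn$family %||% stop_config("config: missing 'synthetic.family'"),
    system = system,
    A = syn$A, A_s = syn$A_s, A_p = syn$A_p,
    chi_fh = syn$chi_fh, size_ratio = syn$size_ratio
  )
}

#' Run the full miscibility analysis pipeline
#'
#' Stages: obtain a chemical-potential profile (from a CSV or the
#' synthetic generator), apply the sigma_mu convergence gate, compute
#' the reduced free energy of mixing, smooth and differentiate it,
#' locate and classify critical points, compute activity coefficients,
#' fit the one-parameter Margules model and cross-validate its predicted
#' spinodals against the detected ones via agreement factors.
#'
#' Configuration list (or path readable by [read_run_config()]):
#' \itemize{
#'   \item `system`: `surfactant`/`polymer` blocks with `name`,
#'     `molecular_weight` (g/mol) and `temperature_C`.
#'   \item exactly one of `input` (profile CSV path) or `synthetic`
#'     (`family` plus model parameters, optional `noise` block with
#'     `sigma_base`, `dilute_inflation`, `cap`).
#'   \item optional: `step_wt_pct` (default 1), `smoothing`
#'     (`method`, `k`, `sp`), `scan_points` (default 1e4),
#'     `agreement_units` (`"wt_pct"` default, or `"chi"`),
#'     `convergence_threshold` (default 0.99), `force` (default FALSE),
#'     `seed` (default 1), `out_dir` (optional; when given, writes
#'     `report.json`, `profile.tsv` and `run.log`).
#' }
#'
#' @param config Configuration list or path.
#' @return A `phasemix_report` (see [classify_stability_limit()])
#'   augmented with `margules`, `agreement`, `convergence`, `system`
#'   and `config` elements.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  system <- config_system(config)
  seed <- as.integer(config$seed %||% 1L)

  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth)
    stop_config("config: exactly one of 'input' and 'synthetic' must be present")

  if (has_input) {
    profile <- read_profile_csv(config$input, system)
    truth <- NULL
  } else {
    model <- config_model(config, system)
    nz <- config$synthetic$noise
    noise <- noise_spec(
      sigma_base = nz$sigma_base %||% 0,
      dilute_inflation = nz$dilute_inflation %||% 1,
      cap = nz$cap %||% 10,
      seed = seed
    )
    grid <- composition_grid(system, config$step_wt_pct %||% 1)
    profile <- generate_profile(model, grid, noise)
    truth <- ground_truth_points(model)
  }

  # convergence gate, per component, joint pass = AND
  thr <- config$convergence_threshold %||% 0.99
  chi <- profile$grid$chi
  gate_s <- sigma_gate(chi, profile$sigma_mu_s, threshold = thr)
  gate_p <- sigma_gate(chi, profile$sigma_mu_p, threshold = thr)
  gate_ok <- gate_s$passed && gate_p$passed
  if (!gate_ok && !isTRUE(config$force))
    stop_typed("phasemix_gate_error",
               "convergence gate failed (R^2 s = %.4f, p = %.4f < %.3f); pass force = TRUE to analyze anyway",
               gate_s$r_squared, gate_p$r_squared, thr)

  fe <- delta_g(profile, system)
  sm <- config$smoothing %||% list()
  curve <- smooth_dg(fe, method = sm$method %||% "auto",
                     k = sm$k %||% 25, sp = sm$sp)
  points <- find_critical_points(curve, system,
                                 scan_points = config$scan_points %||% 1e4)
  report <- classify_stability_limit(points)

  activity <- gamma_from_mu(profile, system)
  mfit <- fit_margules(activity)
  spin_chi <- margules_spinodals(mfit)
  spin_wt <- 100 * mol_to_wt(spin_chi, system)

  units <- config$agreement_units %||% "wt_pct"
  if (!units %in% c("wt_pct", "chi"))
    stop_config("config: agreement_units must be 'wt_pct' or 'chi'")
  det_spin <- points[points$kind == "spinodal", , drop = FALSE]
  agreement <- NULL
  if (nrow(det_spin) && length(spin_chi)) {
    agreement <- do.call(rbind, lapply(seq_len(nrow(det_spin)), function(i) {
      j <- which.min(abs(spin_chi - det_spin$chi[i]))
      s  <- if (units == "wt_pct") det_spin$w_pct[i] else det_spin$chi[i]
      sp <- if (units == "wt_pct") spin_wt[j] else spin_chi[j]
      data.frame(label = det_spin$label[i], detected = s, predicted = sp,
                 factor = agreement_factor(s, sp), stringsAsFactors = FALSE)
    }))
  }

  report$margules <- list(A_s = mfit$A_s, A_p = mfit$A_p,
                          spinodals_chi = spin_chi, spinodals_wt_pct = spin_wt)
  report$agreement <- agreement
  report$agreement_units <- units
  report$convergence <- list(surfactant = gate_s, polymer = gate_p, passed = gate_ok)
  report$system <- system
  report$truth <- truth
  report$profile <- profile
  report$free_energy <- fe
  report$activity <- activity
  report$config <- config
  report$seed <- seed

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# JSON-serializable view of the report
report_to_list <- function(report) {
  lim <- report$stability_limit
  list(
    schema_version = REPORT_SCHEMA_VERSION,
    system = list(
      surfactant = report$system$surfactant$name,
      polymer = report$system$polymer$name,
      temperature_K = report$system$temperature_K
    ),
    convergence = list(
      r_squared_s = report$convergence$surfactant$r_squared,
      r_squared_p = report$convergence$polymer$r_squared,
      passed = report$convergence$passed
    ),
    critical_points = report$critical_points,
    stability_limit = if (is.null(lim)) NULL else as.list(lim),
    mechanism = report$mechanism,
    status = report$status,
    margules = c(report$margules,
                 list(agreement = report$agreement,
                      agreement_units = report$agreement_units)),
    seed = report$seed
  )
}

#' Persist a stability report
#'
#' Writes `report.json` (full precision), `profile.tsv` (chi, w_pct,
#' dg, dg_ideal, dg_excess, gamma_s, gamma_p) and `run.log` (resolved
#' settings; replaying a logged config reproduces the report).
#'
#' @param report A report from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  fe <- report$free_energy
  act <- report$activity
  gs <- rep(NA_real_, nrow(fe$grid)); gp <- gs
  m <- match(round(act$chi, 12), round(fe$grid$chi, 12))
  gs[m] <- act$gamma_s; gp[m] <- act$gamma_p
  tsv <- data.frame(chi = fe$grid$chi, w_pct = fe$grid$w_pct,
                    dg = fe$dg, dg_ideal = fe$dg_ideal, dg_excess = fe$dg_excess,
                    gamma_s = gs, gamma_p = gp)
  utils::write.table(format(tsv, digits = 10, trim = TRUE),
                     file.path(out_dir, "profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log <- c(
    sprintf("phasemix %s", as.character(utils::packageVersion("phasemix"))),
    sprintf("R %s", R.version.string),
    sprintf("seed: %d", report$seed),
    "resolved config:",
    jsonlite::toJSON(report$config, auto_unbox = TRUE, digits = NA, null = "null")
  )
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Write a synthetic profile plus its ground truth
#'
#' Companion to the `simulate` workflow: writes the standard profile CSV
#' and a `truth.json` holding the model parameters and the oracle
#' critical points.
#'
#' @param model A [ground_truth_model()].
#' @param out_dir Output directory.
#' @param grid,noise Passed to [generate_profile()].
#' @return `out_dir`, invisibly.
#' @export
write_synthetic <- function(model, out_dir, grid = NULL, noise = noise_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profile <- generate_profile(model, grid, noise)
  write_profile_csv(profile, file.path(out_dir, "profile.csv"))
  jsonlite::write_json(
    list(family = model$family, parameters = model$pars,
         noise = unclass(noise),
         system = list(surfactant = unclass(model$system$surfactant),
                       polymer = unclass(model$system$polymer),
                       temperature_K = model$system$temperature_K),
         critical_points = ground_truth_points(model)),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  invisible(out_dir)
}
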