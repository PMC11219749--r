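t80_cfg <- function(...) {
  base <- list(
    system = list(
      surfactant = list(name = "Tween 80", molecular_weight = 1309.654),
      polymer = list(name = "Copovidone", molecular_weight = 3818.088),
      temperature_C = 180
    ),
    synthetic = list(family = "margules_one_param", A = 2.84,
                     noise = list(sigma_base = 0)),
    seed = 1
  )
  modifyList(base, list(...))
}

test_that("end-to-end analysis on exact symmetric data reproduces the model", {
  rep <- run_analysis(t80_cfg())
  expect_equal(rep$mechanism, "spinodal")
  expect_equal(rep$stability_limit$chi, SYM284_SPINODAL[1], tolerance = 1e-4)
  expect_equal(rep$margules$A_s, 2.84, tolerance = 1e-6)
  expect_equal(rep$margules$A_p, 2.84, tolerance = 1e-6)
  expect_true(all(rep$agreement$factor > 0.999))
  expect_true(rep$convergence$passed)
})

test_that("a sub-critical mixture is reported fully miscible", {
  rep <- run_analysis(t80_cfg(synthetic = list(family = "margules_one_param",
                                               A = 1, noise = list(sigma_base = 0))))
  expect_equal(rep$mechanism, "fully_miscible")
  expect_null(rep$stability_limit)
  expect_length(rep$margules$spinodals_chi, 0)
})

test_that("reports are reproducible and internally unit-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- t80_cfg(synthetic = list(family = "margules_one_param", A = 2.84,
                                  noise = list(sigma_base = 0.02)))
  cfg$out_dir <- d1
  rep1 <- run_analysis(cfg)
  cfg$out_dir <- d2
  rep2 <- run_analysis(cfg)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(file.exists(file.path(d1, "profile.tsv")))
  expect_true(file.exists(file.path(d1, "run.log")))
  # every reported wt% is the unit twin of its chi
  sys <- rep1$system
  expect_equal(rep1$critical_points$w_pct,
               100 * mol_to_wt(rep1$critical_points$chi, sys), tolerance = 1e-12)
  expect_equal(rep1$margules$spinodals_wt_pct,
               100 * mol_to_wt(rep1$margules$spinodals_chi, sys), tolerance = 1e-12)
})

test_that("the logged configuration replays to the identical report", {
  d1 <- withr::local_tempdir()
  cfg <- t80_cfg(synthetic = list(family = "margules_two_const",
                                  A_s = 4.18, A_p = 2.09,
                                  noise = list(sigma_base = 0.02)),
                 seed = 7)
  cfg$out_dir <- d1
  run_analysis(cfg)
  log <- readLines(file.path(d1, "run.log"))
  replay <- jsonlite::fromJSON(log[length(log)], simplifyVector = TRUE)
  d2 <- withr::local_tempdir()
  replay$out_dir <- d2
  run_analysis(replay)
  j1 <- jsonlite::fromJSON(file.path(d1, "report.json"))
  j2 <- jsonlite::fromJSON(file.path(d2, "report.json"))
  expect_identical(j1, j2)
})

test_that("analysis of a written synthetic CSV matches the in-memory route", {
  d <- withr::local_tempdir()
  sys <- t80_system()
  model <- ground_truth_model("margules_one_param", sys, A = 2.84)
  write_synthetic(model, d, noise = noise_spec(sigma_base = 0.02, seed = 5))
  expect_true(file.exists(file.path(d, "truth.json")))
  cfg <- t80_cfg(seed = 5)
  cfg$synthetic <- NULL
  cfg$input <- file.path(d, "profile.csv")
  rep_csv <- run_analysis(cfg)
  rep_mem <- run_analysis(t80_cfg(
    synthetic = list(family = "margules_one_param", A = 2.84,
                     noise = list(sigma_base = 0.02)), seed = 5))
  expect_equal(rep_csv$stability_limit$chi, rep_mem$stability_limit$chi,
               tolerance = 1e-9)
  expect_equal(rep_csv$margules$A_s, rep_mem$margules$A_s, tolerance = 1e-9)
})

test_that("the convergence gate blocks analysis unless forced", {
  # scattered sigma columns: alternating values cannot be fit smoothly
  d <- withr::local_tempdir()
  sys <- t80_system()
  prof <- generate_profile(ground_truth_model("margules_one_param", sys, A = 2.84),
                           noise = noise_spec(sigma_base = 0))
  n <- length(prof$mu_s)
  prof$sigma_mu_s <- rep(c(0.1, 0.4), length.out = n)
  path <- file.path(d, "profile.csv")
  write_profile_csv(prof, path)
  cfg <- t80_cfg(seed = 1)
  cfg$synthetic <- NULL
  cfg$input <- path
  expect_error(run_analysis(cfg), class = "phasemix_gate_error")
  cfg$force <- TRUE
  rep <- run_analysis(cfg)
  expect_false(rep$convergence$passed)
  expect_equal(rep$mechanism, "spinodal")
})

test_that("configuration errors name the offending field", {
  cfg <- t80_cfg()
  cfg$input <- "also.csv"  # both input and synthetic
  expect_error(run_analysis(cfg), "exactly one", class = "phasemix_config_error")
  cfg2 <- t80_cfg()
  cfg2$system$temperature_C <- NULL
  expect_error(run_analysis(cfg2), "temperature_C", class = "phasemix_config_error")
  cfg3 <- t80_cfg()
  cfg3$system$polymer$molecular_weight <- NULL
  expect_error(run_analysis(cfg3), "molecular_weight", class = "phasemix_config_error")
  cfg4 <- t80_cfg(agreement_units = "mol_pct")
  expect_error(run_analysis(cfg4), "agreement_units", class = "phasemix_config_error")
})

test_that("YAML and JSON configurations load identically", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "system:",
    "  surfactant: {name: Tween 80, molecular_weight: 1309.654}",
    "  polymer: {name: Copovidone, molecular_weight: 3818.088}",
    "  temperature_C: 180",
    "synthetic:",
    "  family: margules_one_param",
    "  A: 2.84",
    "  noise: {sigma_base: 0}",
    "seed: 1"
  ), yml)
  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(read_run_config(yml), auto_unbox = TRUE), jsn)
  r1 <- run_analysis(yml)
  r2 <- run_analysis(jsn)
  expect_equal(r1$stability_limit$chi, r2$stability_limit$chi, tolerance = 1e-12)
})
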