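test_that("noiseless profiles equal the model closed form at every point", {
  sys <- t80_system()
  model <- ground_truth_model("margules_two_const", sys, A_s = 4.18, A_p = 2.09)
  prof <- generate_profile(model, noise = noise_spec(sigma_base = 0))
  chi <- prof$grid$chi
  rt <- rt_kj(sys)
  interior <- chi > 0 & chi < 1
  expect_equal(prof$mu_s[interior],
               -50 + rt * (log(chi[interior]) + 4.18 * (1 - chi[interior])^2),
               tolerance = 1e-12)
  expect_equal(prof$mu_p[interior],
               -100 + rt * (log(1 - chi[interior]) + 2.09 * chi[interior]^2),
               tolerance = 1e-12)
  # component absent at its vanishing endpoint
  expect_true(is.na(prof$mu_s[chi == 0]))
  expect_true(is.na(prof$mu_p[chi == 1]))
  # pure-phase values equal the reference offsets
  expect_equal(prof$mu_s[chi == 1], -50, tolerance = 1e-10)
  expect_equal(prof$mu_p[chi == 0], -100, tolerance = 1e-10)
})

test_that("a fixed seed reproduces a byte-identical profile CSV", {
  sys <- vie_system()
  model <- ground_truth_model("margules_one_param", sys, A = 2.84)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(generate_profile(model, noise = noise_spec(seed = 99)), p1)
  write_profile_csv(generate_profile(model, noise = noise_spec(seed = 99)), p2)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed changes it
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(generate_profile(model, noise = noise_spec(seed = 100)), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("recorded sigma columns follow the documented heteroscedastic law", {
  sys <- eq_system()
  model <- ground_truth_model("margules_one_param", sys, A = 2)
  ns <- noise_spec(sigma_base = 0.05, dilute_inflation = 2, cap = 8, seed = 1)
  prof <- generate_profile(model, noise = ns)
  rt <- rt_kj(sys)
  sd_rt <- prof$sigma_mu_s / rt
  chi <- prof$grid$chi
  i50 <- which(chi == 0.5)
  expect_equal(sd_rt[i50], 0.05, tolerance = 1e-12)        # sigma_base mid-grid
  expect_equal(max(sd_rt), 0.05 * 8, tolerance = 1e-12)    # capped at the ends
  expect_true(all(diff(sd_rt[chi <= 0.5]) <= 1e-12))       # decreasing to mid
  expect_equal(prof$sigma_mu_s, prof$sigma_mu_p, tolerance = 1e-12)
})

test_that("ground-truth oracle reproduces closed-form critical points", {
  sys <- eq_system()
  # symmetric A = 2.84
  m1 <- ground_truth_model("margules_one_param", sys, A = 2.84)
  pts <- ground_truth_points(m1)
  expect_matched(pts$chi[pts$kind == "spinodal"], SYM284_SPINODAL, 1e-8)
  expect_matched(pts$chi[pts$kind == "mechanical"], SYM284_MECHANICAL, 1e-6)
  # sub-critical A = 1: one binodal, nothing else
  p1 <- ground_truth_points(ground_truth_model("margules_one_param", sys, A = 1))
  expect_equal(p1$kind, "binodal")
  expect_equal(p1$chi, 0.5, tolerance = 1e-8)
  # asymmetric printed constants
  pv <- ground_truth_points(ground_truth_model("margules_two_const", sys,
                                               A_s = 4.18, A_p = 2.09))
  expect_matched(pv$chi[pv$kind == "spinodal"], VIE_SPINODAL, 1e-6)
  expect_equal(min(pv$chi[pv$kind == "mechanical"]), VIE_MECHANICAL, tolerance = 1e-6)
})

test_that("the Flory-Huggins family is thermodynamically consistent", {
  sys <- t80_system()
  model <- ground_truth_model("flory_huggins", sys, chi_fh = 1.4, size_ratio = 3)
  prof <- generate_profile(model, noise = noise_spec(sigma_base = 0))
  fe <- delta_g(prof, sys)
  # endpoints exactly zero
  expect_identical(fe$dg[prof$grid$chi == 0], 0)
  expect_identical(fe$dg[prof$grid$chi == 1], 0)
  # excess route equivalence through activity coefficients
  act <- gamma_from_mu(prof, sys)
  interior <- prof$grid$chi > 0 & prof$grid$chi < 1
  route2 <- act$chi * log(act$gamma_s) + (1 - act$chi) * log(act$gamma_p)
  expect_equal(fe$dg_excess[interior], route2, tolerance = 1e-10)
  # oracle derivatives consistent with numerical differentiation of dg
  g <- function(x) o_ideal(x) +
    (1 - x) * log(3) - log(3 - 2 * x) + 1.4 * 3 * x * (1 - x) / (3 - 2 * x)
  expect_equal(fe$dg[interior], g(prof$grid$chi[interior]), tolerance = 1e-12)
  pts <- ground_truth_points(model)
  h <- 1e-6
  for (x in pts$chi[pts$kind == "spinodal"]) {
    num2 <- (g(x + h) - 2 * g(x) + g(x - h)) / h^2
    expect_lt(abs(num2), 1e-2)
  }
})

test_that("noiseless pipeline detection matches the oracle within 1e-4", {
  sys <- t80_system()
  models <- list(
    ground_truth_model("margules_one_param", sys, A = 2.84),
    ground_truth_model("margules_two_const", sys, A_s = 4.18, A_p = 2.09),
    ground_truth_model("flory_huggins", sys, chi_fh = 2.0, size_ratio = 2.5)
  )
  for (model in models) {
    prof <- generate_profile(model, noise = noise_spec(sigma_base = 0))
    fe <- delta_g(prof, sys)
    curve <- smooth_dg(fe)
    det <- find_critical_points(curve, sys)
    truth <- ground_truth_points(model)
    span <- range(prof$grid$chi[prof$grid$chi > 0 & prof$grid$chi < 1])
    truth <- truth[truth$chi >= span[1] & truth$chi <= span[2], ]
    for (kind in c("binodal", "spinodal", "mechanical")) {
      expect_matched(det$chi[det$kind == kind],
                     truth$chi[truth$kind == kind], 1e-4)
    }
  }
})

test_that("noisy spinodal detection errs by less than a grid step in the median", {
  sys <- t80_system()
  model <- ground_truth_model("margules_one_param", sys, A = 2.84)
  truth <- SYM284_SPINODAL[1]
  grid <- composition_grid(sys, 1)
  step <- diff(grid$chi)[which.min(abs(grid$chi - truth))]  # local chi step
  errs <- vapply(1:100, function(s) {
    prof <- generate_profile(model, grid, noise_spec(sigma_base = 0.02, seed = s))
    det <- find_critical_points(smooth_dg(delta_g(prof, sys)), sys)
    sp <- det$chi[det$kind == "spinodal"]
    if (!length(sp)) return(NA_real_)
    min(abs(sp - truth))
  }, numeric(1))
  expect_gt(mean(!is.na(errs)), 0.95)
  expect_lt(median(errs, na.rm = TRUE), step)
})

test_that("invalid model specifications are rejected", {
  sys <- eq_system()
  expect_error(ground_truth_model("van_laar", sys, A = 1),
               class = "phasemix_validation_error")
  expect_error(ground_truth_model("margules_one_param", sys),
               class = "phasemix_validation_error")
  expect_error(ground_truth_model("flory_huggins", sys, chi_fh = 1, size_ratio = 0.5),
               class = "phasemix_validation_error")
  expect_error(noise_spec(sigma_base = -1), class = "phasemix_validation_error")
})
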