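# Independent closed-form oracles used across tests.  These deliberately
# re-derive every quantity from the analytic model formulas rather than
# calling package internals, so the implementation is checked against a
# second route.

# equal-molecular-weight system: mole fraction == weight fraction
eq_system <- function(mw = 1000) {
  binary_system(component("S", mw, "surfactant"),
                component("P", mw, "polymer"),
                temperature_K = 453.15)
}

o_ideal <- function(x) ifelse(x <= 0 | x >= 1, 0, x * log(x) + (1 - x) * log(1 - x))

# two-constant Margules reduced free energy and derivatives
o_margules_dg <- function(x, a_s, a_p) {
  o_ideal(x) + a_s * x * (1 - x)^2 + a_p * x^2 * (1 - x)
}
o_margules_d2g <- function(x, a_s, a_p) {
  1 / (x * (1 - x)) + 6 * x * (a_s - a_p) - 4 * a_s + 2 * a_p
}

# frozen oracle roots (computed by uniroot/closed form on the analytic
# curves at tolerance < 1e-12 before implementation)
SYM284_SPINODAL <- c(0.2280741609, 0.7719258391)   # chi(1-chi) = 1/(2*2.84)
SYM284_MECHANICAL <- c(0.3558765688, 0.6441234312) # dg = 0
VIE_MECHANICAL <- 0.05752254662                    # A_s=4.18, A_p=2.09, dg = 0
VIE_SPINODAL <- c(0.09801825524, 0.64963962969)    # 12.54*chi*(1-chi)^2 = 1

# noiseless chemical-potential profile from explicit lngamma functions
make_profile <- function(system, lngamma_s, lngamma_p, step = 1,
                         mu_s0 = -50, mu_p0 = -100) {
  grid <- composition_grid(system, step)
  rt <- rt_kj(system)
  chi <- grid$chi
  mu_s <- mu_s0 + rt * (log(chi) + lngamma_s(chi))
  mu_p <- mu_p0 + rt * (log(1 - chi) + lngamma_p(chi))
  mu_s[chi == 0] <- NA
  mu_p[chi == 1] <- NA
  chem_potential_profile(grid, mu_s, mu_p)
}

# brute-force critical points of a smoothed curve by dense sign scanning
# (midpoints of 1e6-point brackets; bracket width keeps error < 5e-7)
brute_points <- function(curve, lo, hi, n = 1e6) {
  xs <- seq(lo, hi, length.out = n)
  mids <- function(v) {
    i <- which(v[-length(v)] * v[-1] < 0)
    sort((xs[i] + xs[i + 1]) / 2)
  }
  d0 <- predict(curve, xs, deriv = 0)
  d1 <- predict(curve, xs, deriv = 1)
  d2 <- predict(curve, xs, deriv = 2)
  ext <- mids(d1)
  curv <- predict(curve, ext, deriv = 2)
  list(binodal = ext[curv > 0],
       spinodal = mids(d2),
       mechanical = mids(d0))
}

expect_matched <- function(found, expected, tol) {
  expect_equal(length(found), length(expected))
  if (length(found))
    expect_true(all(abs(sort(found) - sort(expected)) <= tol))
}
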