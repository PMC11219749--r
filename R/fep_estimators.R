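# Desk-scale free-energy estimators for alchemical coupling (lambda)
# windows: Bennett acceptance ratio from forward/reverse work samples,
# one-sided exponential averaging, and window aggregation.  Work values
# are stored in RT units (beta absorbed); this module is a pedagogical
# surrogate feeding chem_potential_profile-scale quantities, not an MD
# engine.

#' Bennett acceptance ratio estimate of a free-energy difference
#'
#' Solves the BAR self-consistency equation
#' `sum_i f(M + W_F_i - dG) = sum_j f(-M + W_R_j + dG)` with `f` the
#' logistic function `1/(1+exp(x))` and `M = log(n_F/n_R)`, by bracket
#' expansion and bisection to `1e-10`.  Under the work-distribution
#' fluctuation relation the estimator is statistically optimal; in the
#' dissipationless limit (all forward work `w`, all reverse work `-w`)
#' it returns exactly `w`.  The reported standard error is Bennett's
#' asymptotic variance evaluated at the solution.
#'
#' @param forward Forward work samples, RT units (non-empty).
#' @param reverse Reverse work samples, RT units (non-empty).
#' @return List of class `phasemix_bar` with `dg` (RT units), `se`,
#'   `n_forward`, `n_reverse`.
#' @export
bar_estimate <- function(forward, reverse) {
  if (!length(forward) || !length(reverse))
    stop_validation("bar_estimate: both work arrays must be non-empty")
  if (any(!is.finite(forward)) || any(!is.finite(reverse)))
    stop_validation("bar_estimate: work values must be finite")
  nf <- length(forward); nr <- length(reverse)
  m <- log(nf / nr)
  logistic <- function(x) 1 / (1 + exp(x))
  h <- function(dg) sum(logistic(m + forward - dg)) - sum(logistic(-m + reverse + dg))
  # h is increasing in dg; expand a bracket around the crude estimate
  lo <- min(-reverse, forward) - 1
  hi <- max(-reverse, forward) + 1
  for (i in 1:60) {
    if (h(lo) < 0) break
    lo <- lo - 2^i
  }
  for (i in 1:60) {
    if (h(hi) > 0) break
    hi <- hi + 2^i
  }
  if (h(lo) >= 0 || h(hi) <= 0 || abs(h(lo) - h(hi)) < .Machine$double.eps)
    stop_convergence("bar_estimate: no self-consistent solution; the forward and reverse work distributions do not overlap -- collect more samples or narrow the window")
  dg <- bisect_root(h, lo, hi, tol = 1e-10, max_iter = 400L)
  # Bennett asymptotic variance from the Fermi-function weights
  a <- logistic(m + forward - dg)
  b <- logistic(-m + reverse + dg)
  if (sum(a) == 0 || sum(b) == 0)
    stop_convergence("bar_estimate: forward and reverse work distributions do not overlap numerically -- collect more samples or narrow the window")
  var_dg <- (sum(a^2) / sum(a)^2 - 1 / nf) + (sum(b^2) / sum(b)^2 - 1 / nr)
  structure(
    list(dg = dg, se = sqrt(max(var_dg, 0)), n_forward = nf, n_reverse = nr),
    class = "phasemix_bar"
  )
}

#' One-sided exponential-averaging estimate
#'
#' `dG = -log(mean(exp(-W)))` from forward work only; the one-sided
#' fallback when no reverse samples exist.  Agrees with [bar_estimate()]
#' in the large-overlap Gaussian limit but converges far more slowly.
#' Standard error by the delta method.
#'
#' @param work Forward work samples, RT units.
#' @return List of class `phasemix_bar` with `dg`, `se`, `n_forward`,
#'   `n_reverse = 0`.
#' @export
exp_estimate <- function(work) {
  if (!length(work) || any(!is.finite(work)))
    stop_validation("exp_estimate: need non-empty finite work samples")
  n <- length(work)
  # stabilized log-mean-exp
  wmax <- max(-work)
  lme <- wmax + log(mean(exp(-work - wmax)))
  ew <- exp(-work - wmax)
  se <- if (n > 1) sqrt(stats::var(ew) / n) / mean(ew) else NA_real_
  structure(
    list(dg = -lme, se = se, n_forward = n, n_reverse = 0L),
    class = "phasemix_bar"
  )
}

#' @export
print.phasemix_bar <- function(x, ...) {
  cat(sprintf("dG = %.6g +/- %.3g RT (n_F = %d, n_R = %d)\n",
              x$dg, x$se, x$n_forward, x$n_reverse))
  invisible(x)
}

#' Aggregate per-window free-energy differences
#'
#' The total coupling free energy is the sum over lambda windows; the
#' standard error combines in quadrature assuming window independence.
#'
#' @param dg Per-window free-energy differences (RT units).
#' @param se Per-window standard errors, same length.
#' @return List with `dg` and `se` of the total.
#' @export
aggregate_windows <- function(dg, se = rep(0, length(dg))) {
  if (!length(dg)) stop_validation("aggregate_windows: need at least one window")
  if (length(se) != length(dg))
    stop_validation("aggregate_windows: dg and se lengths differ")
  list(dg = sum(dg), se = sqrt(sum(se^2)))
}

#' Read lambda-window work samples from CSV
#'
#' Expected columns: `window, direction, work_RT`, with `direction` in
#' `{forward, reverse}`.
#'
#' @param path CSV path.
#' @return A list (one element per window, ordered) of lists with
#'   `forward` and `reverse` numeric vectors.
#' @export
read_work_csv <- function(path) {
  if (!file.exists(path)) stop_validation("read_work_csv: no such file '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("window", "direction", "work_RT")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("read_work_csv: missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(df$direction %in% c("forward", "reverse")))
    stop_validation("read_work_csv: direction must be 'forward' or 'reverse'")
  lapply(split(df, df$window), function(d) list(
    forward = d$work_RT[d$direction == "forward"],
    reverse = d$work_RT[d$direction == "reverse"]
  ))
}
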