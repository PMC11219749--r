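# Internal helpers: typed conditions and root refinement.

stop_typed <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "phasemix_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_domain     <- function(msg, ...) stop_typed("phasemix_domain_error", msg, ...)
stop_validation <- function(msg, ...) stop_typed("phasemix_validation_error", msg, ...)
stop_config     <- function(msg, ...) stop_typed("phasemix_config_error", msg, ...)
stop_convergence <- function(msg, ...) stop_typed("phasemix_convergence_error", msg, ...)

# Plain bisection on a bracketing interval [lo, hi] with f(lo)*f(hi) <= 0.
# Returns the midpoint once the interval is narrower than tol.
bisect_root <- function(f, lo, hi, tol = 1e-10, max_iter = 200L) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop_domain("bisect_root: interval [%g, %g] does not bracket a root", lo, hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if ((hi - lo) <= tol) return(mid)
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Sign-change scan of f over a dense grid; each bracket refined by bisection.
# Roots closer than merge_tol are merged to their mean.
scan_roots <- function(f, lo, hi, n = 1e4, tol = 1e-8, merge_tol = 1e-6) {
  xs <- seq(lo, hi, length.out = n)
  ys <- f(xs)
  ok <- is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 2L) return(numeric(0))
  s <- sign(ys)
  # treat exact zeros as roots directly
  roots <- xs[ys == 0]
  idx <- which(s[-length(s)] * s[-1] < 0)
  for (i in idx)
    roots <- c(roots, bisect_root(f, xs[i], xs[i + 1], tol = tol))
  roots <- sort(roots)
  if (length(roots) > 1L) {
    grp <- cumsum(c(TRUE, diff(roots) > merge_tol))
    roots <- as.numeric(tapply(roots, grp, mean))
  }
  roots
}

`%||%` <- function(a, b) if (is.null(a)) b else a
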