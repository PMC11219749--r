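---
title: "Miscibility screening from chemical-potential profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Miscibility screening from chemical-potential profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasemix)
```

`phasemix` post-processes composition-resolved chemical potentials of a
binary surfactant/polymer blend into a classified miscibility
(stability) limit. This vignette documents the model, the numerical
choices, the synthetic data generator the tests rely on, and the known
limitations.

## The thermodynamic model

All free energies are reduced by RT and expressed per mole of model
molecules. With the pure phases as reference states, the molar Gibbs
free energy of mixing at surfactant mole fraction $\chi$ is

$$\Delta g/RT = \chi\,\frac{\mu_s-\mu_s^0}{RT}
             + (1-\chi)\,\frac{\mu_p-\mu_p^0}{RT},$$

which splits into the ideal part
$\Delta g^I/RT = \chi\ln\chi + (1-\chi)\ln(1-\chi)$ and the excess
$\Delta g^E = \Delta g - \Delta g^I$. The same excess is reachable
through activity coefficients,
$\gamma = e^{(\mu-\mu^0)/RT}/\chi$ and
$\Delta g^E/RT = \chi\ln\gamma_s + (1-\chi)\ln\gamma_p$; the two routes
are algebraically identical, and the test suite asserts their agreement
to $10^{-10}$.

Three kinds of critical points are classified on $\Delta g(\chi)$:
binodal ($\Delta g'=0$, $\Delta g''>0$: single-phase minima), spinodal
($\Delta g''=0$: onset of activationless decomposition) and
mechanical/chemical mixture limits (interior $\Delta g=0$ crossings,
beyond which mixing no longer pays). The physical stability limit is
the lowest-load point of the latter two kinds — binodal minima are
stable compositions and never the limit — and the mechanism is that
point's kind. Both orderings occur in practice: strongly asymmetric
excess models (e.g. $A_s = 4.18$, $A_p = 2.09$) put the mechanical
crossing first, near-symmetric ones (e.g. $A_s \approx A_p \approx
2.84$) put the spinodal first.

The binodal is deliberately defined through local minima rather than a
common-tangent construction; common-tangent equilibria are out of
scope.

## Units and conventions

* Compositions are stored as weight fraction in $[0,1]$; reports print
  wt% $= 100\,w$. The mole fraction axis uses per-model-molecule
  molecular weights, $\chi = (w/M_s)/(w/M_s + (1-w)/M_p)$.
* The gas constant is fixed at 8.314462618 J mol⁻¹ K⁻¹; 180 °C
  converts exactly to 453.15 K.
* Chemical potentials enter files in kJ/mol; internally everything is
  reduced to $(\mu-\mu^0)/RT$ immediately, which removes units from
  every downstream formula.
* Reference potentials default to the measured endpoint values
  ($\chi=1$ for the surfactant, $\chi=0$ for the polymer); explicit
  overrides are accepted when a grid does not reach the endpoints.
* $0\ln 0$ is evaluated as its limit 0, not by epsilon-shifting, so
  $\Delta g$ vanishes identically at the endpoints for
  endpoint-derived references.
* A caveat worth recording: with per-molecule molecular weights of the
  studied components (1984.513/1309.654 g/mol surfactants, 3818.088
  g/mol polymer) the $\chi = 0.5$ composition lies at 34.2 wt%
  (TPGS) and 25.5 wt% (Tween 80). Per-repeat-unit conventions would
  place it elsewhere; only the per-molecule convention is implemented,
  and all reported wt%/χ pairs are exact unit twins of each other.

## Smoothing and differentiation

Spinodal detection requires the *second* derivative of a curve that is
measured with noise and has logarithmically divergent derivatives at
both endpoints. Two design choices address this.

**Only the excess is fitted.** The ideal part and its derivatives
($\ln\frac{\chi}{1-\chi}$, $\frac{1}{\chi(1-\chi)}$) are analytic, so
the spline is fitted to $\Delta g^E$ alone and the ideal part is added
back in closed form. The fitted object is then smooth and bounded on
the whole grid, the endpoint singularities are represented exactly, and
no spurious sign changes appear in the dilute wings where
$1/(\chi(1-\chi))$ dominates.

**The penalty order matches the estimand.** For exact (noise-free)
input the excess is interpolated by a cubic spline
(Forsythe–Malcolm–Moler end conditions, which reproduce a globally
cubic excess — every two-constant Margules model — exactly). For noisy
input a generalized-cross-validated cubic smoothing spline estimates
the *function* well but its second derivative poorly: at the study
conditions (101-point 1 wt% grid, mid-grid noise 0.02 RT) its median
spinodal-location error was well above one grid step. The default
noisy-path smoother is therefore a penalized regression spline
(thin-plate basis, dimension 25) with a penalty on the **third**
derivative, selected by REML and weighted by $1/\sigma_{\Delta g}^2$.
The null space of that penalty contains all quadratics — i.e. the
entire one-parameter Margules excess family — so the curvature estimate
is free of shrinkage bias, and the median spinodal error drops below
half a grid step. The classic GCV cubic spline remains available as
`method = "gcv"`, and a fixed smoothing parameter can be supplied.

Endpoint uncertainties are propagated, not zeroed: the endpoint
$\Delta g$ is pinned to zero only by subtracting a noisy reference, and
treating it as exactly known forces the smoother to near-interpolation
and ruins the curvature estimate.

## Root finding and labelling

Critical points are located by sign-change bracketing on a dense scan
(default $10^4$ points over the interior data range) followed by plain
bisection to $|\Delta\chi| \le 10^{-8}$ ($10^{-10}$ for the analytic
Margules spinodals); roots of the same kind closer than $10^{-6}$ are
merged. Points below the interior maximum of $\Delta g$ are labelled
branch 1 (polymer-rich), the rest branch 2 (surfactant-rich), with a
$\chi<0.5$ fallback when no interior maximum exists. At the marginal
symmetric constant $A = 2$ the curvature touches zero at $\chi = 0.5$
without crossing; the detector then reports a single degenerate point
or none, depending on whether the tangency registers at scan
resolution.

Detection is validated two ways: against a $10^6$-point brute-force
sign scan of the same curve (agreement to $10^{-6}$), and against
closed-form/bisection oracles evaluated on the *analytic* model
curves, independently of any spline.

## The Margules cross-check

The one-parameter constants are fitted by weighted least squares
through the origin of $\ln\gamma_s$ on $(1-\chi)^2$ and $\ln\gamma_p$
on $\chi^2$ over all interior grid points — not by averaging the
pointwise ratios, which blow up near the endpoints. Weights default to
$1/\sigma^2$ when the profile carries uncertainties, else uniform.
Predicted spinodals solve
$1/(\chi(1-\chi)) + 6\chi(A_s-A_p) - 4A_s + 2A_p = 0$. Agreement with
the spline-detected spinodals is quantified as $1-|s'-s|/s$, computed
in wt% by default (configurable to mole fraction); the factor may be
negative and is reported as-is. Richer excess models (two-parameter
Margules, van Laar, NRTL) are deliberately not fitted: the validator
mirrors a one-parameter analysis even when the truth is not of that
form.

## Convergence gate

A profile is analyzed only if its recorded $\sigma_\mu(\chi)$ varies
smoothly with composition: a least-squares cubic B-spline with
$\max(4, \lfloor n/10\rfloor)$ uniform interior knots must reach
$R^2 \ge 0.99$. Degenerate conventions: a constant $\sigma$ array has
$SS_{tot}=0$ and passes with $R^2 = 1$. The gate is applied per
component and both must pass; `force = TRUE` overrides it (the CLI
maps a gate failure to exit code 2). Uniform knots at $j/(k+1)$ nest
across budgets where $k_2+1$ is a multiple of $k_1+1$, making $R^2$
provably non-decreasing along such chains — the property the tests
assert. Whether the fit should run over composition or simulation time
is under-determined by the source method description; composition is
implemented and the choice is configurable only in threshold, knots
and degree.

## The synthetic generator

`generate_profile()` emulates FEP-derived profiles with known truth:

* **Families.** Symmetric/two-constant Margules (quadratic
  $\ln\gamma$ forms) and Flory–Huggins with interaction parameter
  $\chi_{FH}$ and molar size ratio $r \ge 1$ (entropic asymmetry not
  representable by the Margules fit — used to probe robustness of the
  validator against model misspecification).
* **Noise.** Independent Gaussian per point with
  $\mathrm{sd}(\chi) = \sigma_{base}\min\{1 + \lambda(0.5/d - 1),\,
  \mathrm{cap}\}$, where $d$ is the distance to the nearest endpoint
  and $\lambda$ the `dilute_inflation` rate:
  $\sigma_{base}$ (default 0.02 RT) is the mid-grid level, and the
  uncertainty inflates as the annihilated species becomes dilute —
  mimicking the degrading statistics of annihilating a vanishing
  component — capped at 10×. The true sd is recorded in the σ columns.
* **Determinism.** One integer seed governs all randomness; a fixed
  seed reproduces a byte-identical CSV.
* **Conventions.** $\mu_s$ at $\chi=0$ and $\mu_p$ at $\chi=1$ are
  `NA` (the species is absent); reference offsets default to −50 and
  −100 kJ/mol and cancel in every reduced quantity.

What it does **not** emulate: correlated errors across compositions
(FEP windows share configurations), non-Gaussian tails, finite-size
effects, or any atomistic detail. Passing recovery tests therefore
demonstrate the correctness and noise-robustness of the *analysis*,
not the accuracy of any particular simulation engine.

## Problem sizes and runtime choices

The default study conditions are a 101-point 1 wt% grid at 453.15 K.
The stochastic suites use 100 seeded replicates for noisy spinodal
recovery and Margules recovery, 20 random models for the brute-force
detector comparison, and $10^4$ Gaussian work samples per direction
for the BAR check — sizes at which every statistical property tested
is comfortably resolved on a desktop.

## BAR estimator

Work values are stored in RT units. The Bennett self-consistency
equation is solved by bracket expansion plus bisection to $10^{-10}$;
the reported error is Bennett's asymptotic variance at the solution.
The one-sided exponential average is a separate, clearly-labelled
fallback for missing reverse samples. Windows aggregate by summation
with errors in quadrature under an independence assumption. The module
is a desk-scale surrogate: it gives the annihilation→μ leg of the
pipeline a testable embodiment and makes no claim to reproduce
atomistic chemical potentials.

## Known limitations

* Binary mixtures only; no multi-component extension.
* No common-tangent binodal construction, no temperature–composition
  phase diagrams, no nucleation kinetics.
* The stability-limit *mechanism* under noise is less robust than the
  limit location: near-symmetric systems have $|\Delta g|$ of order
  $10^{-2}$ over a wide composition range, so mechanical crossings
  move substantially under 0.02 RT noise even when spinodals are
  stable. Replicated runs (varying the seed) are recommended before
  interpreting the mechanism of a noisy dataset.
* Agreement factors computed from a Margules fit of non-Margules truth
  inherit the model misspecification; they are a consistency check,
  not an error bar.
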