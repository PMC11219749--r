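# phasemix

Thermodynamic miscibility screening for binary polymer–surfactant
(excipient) blends from composition-resolved chemical potentials.

## The problem

Amorphous solid dispersions and hot-melt-extruded placebo blends fail
when the surfactant load exceeds the miscibility limit of the
polymer matrix: beyond that load the mixture phase-separates, which in
drug products promotes recrystallization. Molecular simulation (free
energy perturbation, FEP) can deliver the chemical potentials
μ<sub>s</sub>(χ) and μ<sub>p</sub>(χ) of both components across the
full composition range; `phasemix` turns such profiles into a
classified stability limit.

The pipeline reconstructs the reduced molar Gibbs free energy of
mixing, with the pure phases as reference states,

    Δg/RT = χ (μ_s − μ_s⁰)/RT + (1 − χ) (μ_p − μ_p⁰)/RT

on a 0–100 wt% composition grid (χ is the surfactant mole fraction per
model molecule), splits it into ideal and excess parts

    Δg^I/RT = χ ln χ + (1 − χ) ln(1 − χ),     Δg^E = Δg − Δg^I

and classifies three kinds of critical points on the smoothed curve:

* **binodal** — Δg′ = 0 and Δg″ > 0 (single-phase local minima),
* **spinodal** — Δg″ = 0 (boundary of activationless phase separation),
* **mechanical/chemical mixture limit** — interior Δg = 0 crossings.

The physical stability limit is the lowest-load spinodal or mechanical
point; its kind is the destabilizing mechanism. As an orthogonal check
the same data are reduced to activity coefficients
γ = exp((μ − μ⁰)/RT)/χ, fitted to the one-parameter Margules model
(ln γ_s = A_s(1−χ)², ln γ_p = A_pχ²), whose spinodals follow from

    1/(χ(1−χ)) + 6χ(A_s − A_p) − 4A_s + 2A_p = 0,

and compared to the detected ones through the agreement factor
`1 − |s′ − s|/s`.

The package also ships a desk-scale Bennett acceptance ratio (BAR)
estimator for per-λ-window free-energy differences, a convergence gate
that accepts a profile only when its σ_μ uncertainties vary smoothly
with composition (spline fit with R² ≥ 0.99), and a synthetic generator
of FEP-like profiles (Margules or Flory–Huggins truth plus
heteroscedastic noise) so that every stage has parameter-recovery tests
with known ground truth.

## Worked example

Analyze a synthetic Tween 80 / Copovidone blend at 180 °C whose excess
free energy follows a symmetric Margules model with A = 2.84:

```r
library(phasemix)
cfg <- list(
  system = list(
    surfactant = list(name = "Tween 80",   molecular_weight = 1309.654),
    polymer    = list(name = "Copovidone", molecular_weight = 3818.088),
    temperature_C = 180
  ),
  synthetic = list(family = "margules_one_param", A = 2.84,
                   noise = list(sigma_base = 0)),
  seed = 1
)
run_analysis(cfg)
```

```
Stability report
 label       kind     chi  w_pct          branch
    b1    binodal 0.08773  3.193    polymer_rich
    s1   spinodal 0.22810  9.202    polymer_rich
    m1 mechanical 0.35590 15.930    polymer_rich
    m2 mechanical 0.64410 38.300 surfactant_rich
    s2   spinodal 0.77190 53.720 surfactant_rich
    b2    binodal 0.91230 78.100 surfactant_rich
Stability limit: s1 at 9.202 wt% (chi = 0.2281), mechanism = spinodal
```

Reading: the blend is single-phase up to the lower binodal b1
(3.2 wt%), the physical stability limit is the lower spinodal s1 at
9.2 wt% surfactant (χ = 0.228, matching the closed form
χ(1−χ) = 1/(2A)), and the destabilizing mechanism is spinodal
decomposition — the mechanical mixture crossing m1 lies higher, at
15.9 wt%. With the asymmetric constants A_s = 4.18, A_p = 2.09 the
ordering reverses and the limit is a mechanical/chemical mixture
threshold. The fitted Margules constants and the agreement factors
between the two spinodal routes are in `$margules` and `$agreement` of
the returned report; with exact input both factors are 1.000.

A thin command-line front end with `simulate`, `analyze`, `margules`,
`bar` and `convert` subcommands is installed under `inst/cli/phasemix`:

```sh
Rscript inst/cli/phasemix analyze --config cfg.yaml --out out/
```

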