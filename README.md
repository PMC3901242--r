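# nmrkin — enzyme kinetics from NMR progress curves

Classical enzyme kinetics fits initial rates to the irreversible
Michaelis–Menten equation, discarding most of each time course and all
information about reversibility, cooperativity and allosteric control.
`nmrkin` implements the alternative: globally fitting **generalized
(reversible) Hill rate laws** to whole **³¹P-NMR progress curves**, in which
every phosphorylated substrate, product and effector of an assay is
quantified simultaneously in real time. The package targets kineticists and
systems-biology modellers who need operationally defined parameters
(half-saturations, Hill coefficient, modifier effect, equilibrium constant)
for ODE models — demonstrated end to end on the first two glycolytic
enzymes of *E. coli*, phosphoglucose isomerase (PGI) and
phosphofructokinase (PFK).

## The method

1. **FID processing** — arrays of free-induction decays are exponentially
   apodized (`apodize_exponential`, 8.5 Hz by default), Fourier-transformed
   (`fid_to_spectrum`) and quantified per peak window by box integration or
   Lorentzian deconvolution (`integrate_window`,
   `deconvolve_lorentzians`). Concentrations come from the ratio to an
   internal triethyl-phosphate (TEP) standard with T1 saturation
   correction (`quantify_series`, `saturation_correction`).
2. **Rates from splines** — each species' progress curve is fitted
   independently (mass conservation is never assumed) with a cubic
   smoothing spline (`fit_smoothing_spline`) and differentiated; the
   reaction rate at each measured time is the stoichiometry-signed mean of
   the available species derivatives (`rates_from_splines`). Obscured
   species can be inferred from equilibrium with a fast isomerase
   (`infer_equilibrium_species`), pre-equilibration data are split off for
   validation (`exclude_pre_equilibration`), and sessions are made
   comparable by maximal-rate normalization (`normalize_to_reference`).
3. **Global fitting** — pooled rate samples from all assays are fitted with
   a rate law from the pluggable registry. For PGI the uni-uni reversible
   Hill equation (reversible Michaelis–Menten at *h* = 1):

   v = Vf σ (1 − Γ/Keq) (σ+π)^(h−1) / (1 + (σ+π)^h),
   σ = [S]/S₀.₅, π = [P]/P₀.₅, Γ = [P]/[S]

   For PFK an irreversible bi-substrate Hill equation with PEP as negative
   allosteric modifier:

   v = Vf (σ₁σ₂)^h / (M + σ₁^h + σ₂^h + (σ₁σ₂)^h),
   M = (1 + μ^h) / (1 + α μ^h)

   `fit_global` runs a seeded genetic algorithm over the log-parameter box
   and refines with multi-start Levenberg–Marquardt; errors come from the
   residual-variance-scaled covariance (`parameter_errors`), fit quality
   from R² (`goodness_of_fit`). The Haldane relationship ties the reverse
   maximal rate to the forward parameters (`haldane_reverse_vmax`), and
   `truncation_scan` probes how estimates and errors react as
   near-equilibrium data are removed.
4. **Validation by simulation** — a minimal coupled PGI–PFK model with
   Mg²⁺–nucleotide rapid equilibria and background MgADP hydrolysis
   (`minimal_model`, `simulate_minimal_model`, `mg_partition`) predicts
   held-out time-course segments (`compare_to_experiment`); SBML
   export/import (`write_sbml`, `read_sbml`) connects to standard
   simulators.
5. **Synthetic data** — `pgi_scenario`/`pfk_scenario` +
   `simulate_noisy_timecourses` generate noisy progress curves from known
   parameters, and `synthesize_fid_series` builds complete synthetic FID
   series, so the whole pipeline is testable without spectrometer data.

## Worked example

Simulate one noisy PGI session (five assays, 3 % multiplicative noise) and
refit the rate law:

```r
library(nmrkin)

sim   <- simulate_noisy_timecourses(
           pgi_scenario(noise = noise_model(conc_mult_sd = 0.03), seed = 11))
rates <- build_rate_dataset(sim$curves, pgi_scheme(),
           smoothing = function(cv) 0.5 * mean((0.03 * cv$conc)^2))
fit   <- fit_global(global_fit_problem("pgi", rates,
           free  = c(vf = 0.5, k_G6P = 0.3, k_F6P = 0.3, keq = 0.5),
           fixed = c(h = 1), seed = 11))
print(fit)
#> global fit of 'pgi' law: 200 samples, 4 free parameters
#>       estimate      sem
#> vf     0.31014 0.026397
#> k_G6P  0.25644 0.334633
#> k_F6P  0.07903 0.099508
#> keq    0.28590 0.003849
#> fixed: h = 1
#> RSS 0.1325, R^2 0.9319, converged: TRUE

haldane_reverse_vmax(pgi_table_params())
#> [1] 3.431354
```

Reading the output: the equilibrium constant is pinned almost exactly
(0.2859 ± 0.004; the near-equilibrium tail of every assay constrains it),
while a single noisy session leaves the half-saturation constants with
standard errors comparable to the estimates themselves — the known weak
spot of progress-curve designs whose concentrations rarely dwell near the
half-saturating region. Volumetric `vf` (mM/min at the scenario's
0.1 mg/mL protein) divided by the protein concentration gives the specific
activity, here 3.10 µmol·min⁻¹·mg⁻¹ against a generating value of 3.551.
With noiseless data the same pipeline recovers all parameters to better
than 1 % (see below). The Haldane value is the reverse maximal rate implied
by the forward fit.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/nmrkin.R fit      --data rates.csv --config fit.yaml --out fit.json
Rscript inst/cli/nmrkin.R scan     --data rates.csv --config fit.yaml --max-remove 10 --out scan.csv
Rscript inst/cli/nmrkin.R simulate --sbml model.xml --t-end 60 --out traj.csv
Rscript inst/cli/nmrkin.R quantify --fid-json fids.json --tep 10 --out curves.csv
```

## Package layout

- `R/rate-laws.R`, `R/registry.R` — rate-law library and pluggable registry
- `R/nmr.R` — FID containers, transform, quantification, Varian/JSON I/O
- `R/progress.R` — splines, rate extraction, equilibration handling,
  normalization
- `R/fitting.R` — GA + LM global fitting, errors, R², truncation scans
- `R/simulation.R`, `R/sbml.R` — minimal coupled model, SBML exchange
- `R/synthetic.R` — scenario generators for curves and FIDs
- `vignettes/progress-curve-kinetics.Rmd` — the methods vignette
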