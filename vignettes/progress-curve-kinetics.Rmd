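---
title: "Progress-curve enzyme kinetics from NMR time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progress-curve enzyme kinetics from NMR time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrkin)
```

# Scope and assumptions

`nmrkin` estimates the parameters of generalized (reversible) Hill rate
laws from metabolite progress curves, with ³¹P-NMR as the intended
measurement modality. The central assumptions are:

* the enzyme activity is constant over the time course (no denaturation,
  no product-dependent inactivation) — the rate at any instant is a
  function of the instantaneous concentrations only;
* every species the rate law needs is either quantified directly, inferred
  from a fast equilibrium, or held at a known level;
* noise acts on the measured concentrations, not on time.

Under these assumptions a progress curve is a trajectory of an autonomous
ODE, and its time derivative at each measured point is a valid sample of
the rate law evaluated at the measured concentration vector. That is the
representation everything downstream uses: a *rate sample* pairs one rate
with one complete concentration vector.

# Rate laws

Two members of the reversible Hill family are built in, and the registry
(`define_rate_law`, `register_rate_law`) accepts any other algebraic form
without changes to the fitter.

**Uni-uni reversible Hill** (PGI; reversible Michaelis–Menten at
$h = 1$):
$$v \;=\; V_f\,\sigma\,(1-\Gamma/K_{eq})\,
  \frac{(\sigma+\pi)^{h-1}}{1+(\sigma+\pi)^h},
  \qquad \sigma = \frac{[S]}{S_{0.5}},\;
  \pi = \frac{[P]}{P_{0.5}},\; \Gamma = \frac{[P]}{[S]}.$$
The numerator is evaluated as $V_f(\sigma - [P]/(S_{0.5}K_{eq}))$, which is
algebraically identical but finite at $[S]=0$; at $[S]=[P]=0$ the
mass-action ratio is defined as 0 and the rate is 0. The sign of $v$ always
equals the sign of the thermodynamic driving force $1-\Gamma/K_{eq}$, and
the Haldane relationship $V_r = V_f P_{0.5}/(S_{0.5}K_{eq})$
(`haldane_reverse_vmax`) makes the implied reverse maximal rate explicit.

**Bi-substrate irreversible Hill with one allosteric modifier** (PFK, PEP
inhibitor):
$$v \;=\; V_f\,\frac{(\sigma_1\sigma_2)^h}
  {M + \sigma_1^h + \sigma_2^h + (\sigma_1\sigma_2)^h},
  \qquad M = \frac{1+\mu^h}{1+\alpha\,\mu^h}.$$
The modifier term $M$ occupies the position of the constant 1 — the
modifier acts on the free-enzyme term, as in the uni-substrate reversible
Hill equation — and the modifier exponent is the reaction's $h$ (not
separately fitted). Two consequences of this form matter in practice and
are worth stating plainly:

* at saturating substrate ($\sigma_i^h \gg M$) the modifier effect
  vanishes; an experiment meant to determine $M_{0.5}$ and $\alpha$ must
  therefore include data where the substrate terms are not overwhelming
  and where the modifier concentration *sweeps through* its
  half-saturation region;
* for a declared inhibitor ($\alpha < 1$) the pair $(M_{0.5}, \alpha)$ has
  a weak-inhibition ridge ($M_{0.5} \to \infty$ or $\alpha \to 1$) that is
  locally indistinguishable when the data barely express inhibition.
  Constraining $\alpha \le 1$ for a modifier declared inhibitory in the
  reaction scheme is the recommended problem configuration.

Because the exact published algebraic grouping of the bi-substrate
denominator is not uniquely determined by its summary description, the
form above is a documented reconstruction: it reduces to the
single-substrate Hill curve when the other substrate saturates, gives
$V_f/4$ at $\sigma_1=\sigma_2=1$ without modifier, and is neutral at
$\alpha = 1$. The registry exists precisely so an alternative grouping can
be swapped in and refitted without touching any other component.

**Units.** $V_f$ is stored as specific activity
(µmol·min⁻¹·mg⁻¹) and converted to volumetric rate (mM·min⁻¹) through the
protein concentration (mg·mL⁻¹; 1 µmol/mL = 1 mM). $K_{eq}$ is
dimensionless. The five-fold effective-ATP correction for Mg²⁺-limited
assays is the exact rescaling identity: dividing a substrate's
concentration and its half-saturation by the same factor leaves every rate
unchanged, so refitting with effective ATP = total/5 maps
$ATP_{0.5} \mapsto ATP_{0.5}/5$ and nothing else.

# NMR processing

The transform chain is deliberately plain: exponential apodization
(default 8.5 Hz line broadening), zero-filling to twice the next power of
two, discrete Fourier transform with the first point halved (suppressing
the DC offset of a sampled decay), zero/first-order phasing (numeric, or
`"auto"` by minimizing negative intensity), optional polynomial baseline.
Quantification is the internal-standard ratio
$$c_{sp} = \frac{A_{sp}}{A_{std}}\; c_{std}\;
  \frac{f_{sp}}{f_{std}}\; \frac{n_{std}}{n_{sp}},$$
with areas summed over all windows of a species, $n$ the ³¹P counts, and
$f$ the T1 saturation corrections
$f = (1-E\cos\theta)/(1-E)$, $E = e^{-T_R/T_1}$ — the steady-state factor
for repetition time $T_R$ and pulse angle $\theta$, which for a 90° pulse
reduces to $1/(1-E)$. The standard's concentration is metadata supplied
per assay, never a constant of the package.

Two quantification routes are provided. Box integration is linear and
robust; its tail truncation cancels in the standard ratio when line widths
match, but tails of *neighbouring* peaks bleed into narrow windows — the
F6P resonance sitting between the FBP anomer doublets is the canonical
case. Lorentzian deconvolution (`deconvolve_lorentzians`,
Levenberg–Marquardt with non-negative areas, auto-seeded from local
maxima) resolves such overlap, and an optional local *linear* baseline
absorbs the residual tails of peaks outside the window. A practical noise
note: exponential apodization correlates spectral noise over roughly one
line width, so the variance of a window integral is an order of magnitude
larger than the white-noise formula suggests; the test suite measures the
area-noise floor empirically from signal-free windows rather than
propagating per-point noise.

File formats: a portable JSON serialization of FID series (the synthetic
interchange format), and a minimal reader/writer for the Varian-style
`fid`/`procpar` directory layout (big-endian int16/int32/float32 blocks).

# From curves to rate samples

Each species is spline-fitted independently; conservation is *reported*
(`conservation_defect`), never enforced. The smoothing level is the one
genuinely consequential tuning choice in the pipeline:

* **Default: generalized cross-validation.** Noise-free data are
  interpolated exactly (an `fmm` cubic spline), noisy data are smoothed.
  A residual-target policy based on second differences was evaluated and
  rejected as the default because curvature leaks into second differences:
  on noiseless fast transients it produced a double-digit-percent
  derivative bias.
* **Derivative-oriented override.** When the noise level is known,
  `smoothing` accepts a target mean squared residual, and the smoothing
  parameter is root-searched to match it. For *derivative* estimation we
  deliberately set the target to **half** the known noise variance:
  GCV-style smoothing, optimal for the function, over-smooths the
  derivative, clipping the extreme rates that determine $V_f$ and biasing
  it low with an overconfident error bar. Under-smoothing trades that bias
  for extra variance which the residual-scaled covariance then reports
  honestly: in the package's replicate studies this restores ≥ 90 %
  coverage of truth within three reported standard errors for every
  parameter.

Rates are sampled at the measured time points; the first and last sample
of each assay carry weight 0.5 (spline derivatives are least reliable at
the interval ends). Species consumed by extraneous activities of a cell
extract (ADP by background hydrolysis; ATP when pyruvate kinase maintains
it) are excluded from the rate average but retained in the concentration
vector.

**Pre-equilibration exclusion.** For coupled assays, the downstream
reaction is fitted only after the fast isomerase has equilibrated: the
boundary is the earliest time after which $|[P]/[S] - K_{eq}|/K_{eq}$
stays within `rel_tol` (default 0.05). The removed points are returned
separately — they are the validation segment, not waste.

**Maximal-rate normalization.** Sessions are made comparable by dividing
by a reference maximal rate. The default estimator extrapolates the rate
to $t = 0$ (quadratic in time over the early window: first time quartile,
capped at 20 % conversion of the dominant species) rather than averaging
over a window: an isomerase with a small product half-saturation starts
self-inhibiting immediately, and a window average therefore
underestimates a *faster* extract by *more*, defeating the purpose of
normalization. The plateau-median variant remains available for reactions
whose rate genuinely plateaus. A reference assay should be acquired on a
short, dense schedule so the initial rate is resolvable.

# Global fitting

`fit_global` is a two-stage optimizer over log-parameters (positivity by
construction; default bounds $10^{\pm 3}$ around the initial guess):

1. a seeded genetic algorithm (population 64, tournament size 2, uniform
   crossover rate 0.7, per-gene Gaussian mutation in log space
   (sd 0.3, rate 0.4), elitism 2, 200 generations; equal-fitness ties
   resolved by lowest index, so runs are bitwise reproducible);
2. multi-start Levenberg–Marquardt refinement: besides the GA optimum, LM
   also starts from the GA optimum with each half-saturation parameter
   reset to every decade inside its bounds. Half-saturations are where
   saturation-type laws are multimodal — a half-saturation far above the
   sampled range is locally as good as any other large value — and the
   decade scan crosses those ridges deterministically at the cost of a few
   extra LM runs.

The refined solution is accepted only if it does not worsen the GA
optimum; otherwise the GA solution is returned flagged unconverged.
Non-finite model values become large penalty residuals rather than
crashes. Standard errors are
$\sqrt{\mathrm{diag}\,( (J^\top J)^{-1}\, RSS/(n-p) )}$ with $J$ the
numeric Jacobian at the solution; an SVD guard reports unidentifiable
directions as infinite errors instead of silent numbers. $R^2$ is computed
over the pooled observed rates.

`truncation_scan` refits after deleting the $k$ latest (nearest to
equilibrium) samples of *every* assay, $k = 1, 2, \dots$, warm-starting LM
from the baseline solution, and reports each step's errors under two
degrees-of-freedom conventions — rescaled ($n_k - p$) and original
($n_0 - p$) — separating the cost of losing data in general from the cost
of losing near-equilibrium data specifically. On the package's synthetic
PGI data the $K_{eq}$ error inflates super-linearly (over an order of
magnitude by deep truncation) while point estimates stay put; the
irreversible PFK fit is insensitive to the same treatment. The truncation
unit is per-assay points; the pooled removed count is reported alongside,
since a pooled-count convention is equally defensible.

# The minimal coupled model

The validation model couples the two fitted laws with the nucleotide
chemistry an extract imposes: ATP and ADP bind Mg²⁺ in rapid equilibrium
(association constants $10^4$ and $10^3\ \mathrm{M^{-1}}$), free Mg²⁺ is
clamped at 1 mM (a total-Mg balance is deliberately not tracked; the
clamp matches the modelled condition and avoids a stiff fast subsystem —
speciation is substituted algebraically at every derivative evaluation),
PFK sees MgATP as its ATP pool (with the Mg-corrected half-saturation),
and a background hydrolysis consumes MgADP to AMP + Pi + Mg²⁺ with
$k = 2\times10^{-4}\ \mathrm{min^{-1}}$. Two hydrolysis conventions exist
in the source material — rate proportional to MgATP (background ATPase
balanced by adenylate kinase) or to MgADP (elementary decay) — both are
implemented (`hydrolysis = "mgatp"`/`"mgadp"`, default `"mgatp"`), and
neither is presented as ground truth. Integration uses `deSolve`'s lsoda
with tight tolerances (`rtol` $10^{-9}$, `atol` $10^{-10}$); adenylate and
hexose totals are conserved to solver precision, and the test suite
cross-checks the trajectory against an independent fixed-step RK4
integration. `write_sbml`/`read_sbml` exchange the model as SBML L3V1
with MathML kinetic laws generated from the same expressions (a minimal
writer for this model family, not a general SBML engine).

# What the synthetic generator does and does not emulate

`simulate_noisy_timecourses` integrates the chosen law under its scheme
stoichiometry and adds seeded multiplicative (default 3 %) and additive
noise, clipping negatives to zero with a flag. Scenario defaults are the
study conditions of the package's round-trip experiments, chosen once:

* **PGI**: five assays at (G6P, F6P)₀ = (10, 0), (5, 0), (2, 0), (0, 8.5),
  (0, 4) mM, 0.1 mg/mL protein, each sampled with 40 blocks from 0.5 min
  to ~110 % of its own equilibration time (12–70 min) — the time scale of
  a real ³¹P time course at that activity, with each assay's schedule
  matched to its kinetics as an experimenter would;
* **PFK**: six assays crossing F6P ∈ {3, 10} × ATP ∈ {2.5, 5} × PEP ∈
  {0, 4, 8} mM at 1 mg/mL, 100 blocks over 75 min (45 s of transients per
  block). A pyruvate-kinase side reaction recycles ADP + PEP → ATP at the
  PFK rate scaled by a PEP Michaelis term (K = 0.3 mM), so PEP *declines*
  through its half-saturation region while ATP is maintained — the innate
  effector perturbation that makes $PEP_{0.5}$ and $\alpha$ identifiable
  at all (static PEP at 4–8 mM is saturating and uninformative under this
  rate-law family).

`synthesize_fid_series` inverts the quantification chain: each species
contributes decaying complex exponentials at its mapped shifts (FBP as a
quartet with two ³¹P, ATP/ADP multiplets, TEP as the constant standard),
attenuated by the pulse sequence's saturation factor, plus complex
Gaussian noise (`fid_noise_sd ≈ 2` gives spectral SNR ≈ 50 for a 5 mM
single-phosphorus species under the default scale).

Passing round trips on these data demonstrate the *pipeline's*
correctness — generation, quantification, differentiation and fitting are
mutually consistent and recover known ground truth (noiseless, to better
than 1 %). They do not demonstrate robustness to what the generator omits:
phase and baseline distortions, lock drift, field inhomogeneity,
J-coupling fine structure, chemical-shift drift with Mg²⁺ titration, or
enzyme inactivation. Real-data use should treat those as open validation
questions.

# Numerical choices and degenerate inputs

* Spline fits require ≥ 4 valid points and refuse silently short curves by
  name. Rate-sample times outside the common spline support are skipped
  with a message.
* A vanishing internal-standard area marks the block invalid and excludes
  it with a log entry; negative concentrations are clipped to zero and
  flagged, never fitted as negative.
* The equilibration criterion that never holds flags the whole assay;
  nothing is silently retained. The boundary is monotone in `rel_tol`.
* Deconvolution on a flat window returns zero areas flagged degenerate;
  non-convergence warns with the residual norm.
* Zero-variance datasets make $R^2$ an error, not an `NaN`.
* GA candidate ties break to the lowest index; identical problem + seed
  reproduce results bitwise.
* `n ≤ p` problems are rejected up front; rank-deficient Jacobians yield
  infinite standard errors on the unidentifiable directions plus a flag.

# Problem sizes used by the shipped studies

The round-trip experiments run at the scenario defaults above (200 pooled
PGI samples, 600 pooled PFK samples). The statistical-calibration studies
use 100 seeded replicates of the five-assay PGI scenario — at 5 %
multiplicative noise for the three-standard-error coverage study and at
the generator's default 3 % for the spread-versus-reported-error
comparison, each with a reduced search budget (60 generations, population
48) appropriate for a four-parameter unimodal problem. Truncation scans
remove up to 34 of 40 points per PGI assay and 24 of 100 per PFK assay.

# Known limitations

* The bi-substrate Hill grouping is a reconstruction (see above); results
  for $PEP_{0.5}$ and $\alpha$ are conditional on it.
* Modifier-parameter identifiability requires effector sweeps; with static
  saturating effector levels the weak-inhibition ridge is reported as
  large/infinite standard errors rather than resolved.
* The spline-derivative estimator degrades gracefully but measurably with
  noise: at 5 % concentration noise half-saturation estimates are
  heavy-tailed across replicates, and their spread can exceed the mean
  reported standard error by more than the factor ~1.5 seen at 3 %.
* The Varian reader covers the plain single-trace layouts the writer
  produces and typical spectrometer output, not every historical variant.
* `read_sbml` restores only models written by `write_sbml`.
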