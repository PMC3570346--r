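---
title: "Quantifying TSPO PET neuroinflammation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TSPO PET neuroinflammation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspopet)
library(dplyr)
```

## The measurement problem

Activated microglia overexpress the 18 kDa translocator protein (TSPO), so
a TSPO-specific radioligand imaged with dynamic PET reports on brain
inflammation in vivo — for instance during epileptogenesis after
kainic-acid-induced status epilepticus (KASE) in the rat, where seizure-prone
regions (hippocampus, amygdala, thalamus, piriform cortex) inflame within
days. Because no brain region is free of TSPO, there is no reference region:
quantification needs an arterial input function, and the tracer's rapid
metabolism means that plasma radioactivity must be corrected down to the
fraction still attributable to intact parent compound.

`tspopet` implements that full quantification chain, plus the terminal
in-vitro arm (film autoradiography with densitometric calibration) and the
group statistics, and pairs it with a synthetic-cohort generator so every
stage is testable against known ground truth.

## Blood processing

Gamma-counted blood and plasma aliquots are decay-corrected
(`decay_correct()`, factor $2^{(t - t_{ref})/T_{1/2}}$ with
$T_{1/2} = 109.77$ min for F-18) and weight-normalised
(`normalize_sample()`, dividing by `weight / density`; plasma density
defaults to 1.03 g/ml).

The parent fraction is modelled as a two-phase exponential decay
$$f(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} + c,$$
in percent, fitted by unweighted nonlinear least squares
(`fit_parent_fraction()`). Two numerical choices matter:

* **Constraint at $t=0$.** By default the curve is constrained through
  100% at injection ($A_1 + A_2 + c = 100$): a just-injected tracer is
  entirely unmetabolised. The constraint can be released.
* **Variable projection.** The amplitudes enter the model linearly, so they
  are profiled out by linear least squares and the nonlinear search runs
  over $(\lambda_1, \lambda_2)$ only, started from a decade-spaced grid.
  Ties are broken by lowest residual, then lowest $\lambda_1$. This makes
  the fit deterministic and robust without per-dataset tuning.

Between-group differences in metabolism are tested with the
extra-sum-of-squares F test (`compare_parent_fits()`): one shared curve
against per-group curves. Under identical truth the test holds its nominal
type-I error (checked by simulation in the test suite).

## The input function

The kinetic model needs continuous curves, while blood is sampled
discretely (every 15 s to 4 min, then 10, 20, 30 and 50 min by default).
Two constructions are provided:

* `interpolate_input()` — piecewise-linear to the peak, log-linear after it
  (positivity-preserving for exponential washout), anchored at zero at
  $t=0$, exact at every sample. Beyond the last sample the tail continues
  exponentially with the washout rate of the final segment (a constant tail
  is available by flag). Interpolation is transparent but pays for sparse
  late sampling: across the 4→10→20→30→50 min gaps the log-linear chord
  overshoots the curved log-decay, carrying roughly 3% error in the input
  integral.
* `fit_input()` — linear rise plus a post-peak sum of three exponentials
  (amplitudes profiled, rates optimised from fixed multi-starts). On the
  same sampling design the input integral is recovered to about 0.1%, and
  the fitted tail extrapolates naturally past the last sample to the end of
  the scan.

`run_study()` defaults to `fit_input()`; that choice is what lets the
zero-noise pipeline recover every ground-truth $V_t$ to well under 0.5%.
Whether to interpolate or fit a sparsely sampled input is a genuinely open
design point in small-animal PET; both routes are exported and tested.

## Kinetic model

Tissue kinetics follow the one-tissue compartment model
$$\frac{dC_t}{dt} = K_1 C_p(t) - k_2 C_t(t),$$
with $C_p$ the metabolite-corrected plasma activity. A VOI also contains
blood, so the modelled signal is
$$C(t) = (1 - V_b)\,K_1 \!\int_0^t e^{-k_2 (t-s)} C_p(s)\,ds + V_b\,C_{wb}(t),$$
with the vascular fraction fixed at $V_b = 0.05$ (not estimated). The
endpoint is the volume of distribution $V_t = K_1 / k_2$, the equilibrium
tissue-to-plasma ratio of a reversible tracer.

Numerics:

* **Convolution.** `model_tac()` evaluates the convolution exactly for a
  piecewise-linear $C_p$ on a uniform grid (0.25 s step by default, 0.05 s
  in the oracle tests) via a recursive filter — the discretisation error is
  quadratic in the step. Reported values are frame averages, matching how a
  scanner histogram integrates counts over each frame; the default schedule
  is 28 frames (8×15 s, 6×20 s, 6×60 s, 3×180 s, 5×500 s; 3640 s).
* **Estimation.** `fit_1tc()` minimises weighted least squares over
  $(K_1, k_2)$ with frame-duration weights by default (uniform by flag).
  The model is linear in $K_1$ given $k_2$, so $K_1$ is profiled by
  weighted linear regression and the search reduces to a 1-D problem in
  $\log k_2$: a 17-point log-spaced scan over $k_2 \in [10^{-4}, 10]$
  min$^{-1}$ followed by Brent refinement. This variable-projection form is
  equivalent to a 2-D bounded multi-start search but deterministic and an
  order of magnitude faster; $K_1$ is clamped to $(0, 10]$.
* **Uncertainty.** Standard errors come from the local Jacobian; the
  $V_t$ SE uses the delta method.

Delay and dispersion between the femoral sampling site and the brain are
not modelled — a known limitation of the design this package mirrors.

## The simplified ratio r50′

`compute_r50()` implements the non-invasive surrogate endpoint: the
duration-weighted mean VOI activity over the frames overlapping a late
window (49–54 min by default; frames are weighted by their overlap with the
window, since frame boundaries need not align with it) divided by the
metabolite-corrected plasma activity at 50 min. The denominator defaults to
the measured 50-min sample corrected with its own terminal metabolite
analysis (r50′); correcting with the fitted standard curve instead gives
r50′(SC), and the two coincide exactly when the standard curve predicts the
terminal sample's parent fraction. For a one-tissue system at true
equilibrium the ratio equals $V_t$; during a real scan it is a transient
that approaches $V_t \cdot k_2 / (k_2 - \lambda)$ for a terminal plasma
clearance rate $\lambda$, which is why the package (and its tests) treats
r50′ as a correlate of $V_t$, not an unbiased estimate.

## Autoradiography

Film autoradiograms are calibrated against co-exposed polymer standards
with a cubic fit of activity on optical density (`fit_calibration()`),
fitted in the forward direction used for quantification. The fit is
rejected unless strictly monotone increasing over the standards' OD range,
and evaluation outside that range errors — mirroring the requirement that
section ODs stay within the film's pseudolinear response. ROI optical
densities are calibrated first and then averaged over replicate (typically
triplicate) sections; specific binding is total minus non-specific (from
sections co-incubated with 10 µM PK11195), with negative differences
retained and warned about rather than floored.

## Group statistics

`t_test_auto()` follows the convention of choosing the t-test variant from
the data: a two-sided F test of variance equality at α = 0.05 selects
pooled-variance Student or Welch. `anova_tukey()` wraps one-way ANOVA with
Tukey HSD (Tukey–Kramer when unbalanced); `pearson_r()` reports $r$ with
the t-transform p value; `percent_difference()` is
$(\mathrm{treated} - \mathrm{control})/\mathrm{control} \times 100$ on
unrounded means. Significance is flagged at 0.05 and a trend at 0.1; no
multiple-testing correction is applied across regions, deliberately
mirroring the analysis convention this package reproduces. Report tables
round for display only ($V_t$ to one decimal, percent increase to an
integer); raw outputs keep full precision.

## The synthetic cohort

`simulate_cohort()` generates the study the analysis assumes:

* whole-blood activity rising linearly over a 1-min constant infusion, then
  clearing bi-exponentially (defaults 150 and 15 kBq/ml at 0.8 and 0.02
  min$^{-1}$ — a realistic peak for a ~20 MBq rat study), with a constant
  plasma-to-whole-blood ratio of 1.3;
* a parent-fraction curve with $A_1 = 55$%, $\lambda_1 = 0.25$ min$^{-1}$,
  $A_2 = 45$%, $\lambda_2 = 0.0165$ min$^{-1}$, i.e. ≈20% parent at 50 min,
  matching the terminal-sample metabolism of the tracer class modelled;
* two groups (control and KASE, $n = 4$ each) whose per-region true $V_t$
  are drawn from the configured means and SDs — the default table carries
  the region-by-hemisphere group means of the study being emulated, with
  between-animal SD = SEM·√n — and per-animal $k_2 = K_1 / V_t$ with
  $K_1 = 0.3$ ml·ml$^{-1}$·min$^{-1}$;
* frame noise that is zero-mean Gaussian with variance proportional to
  activity over frame duration (the standard count-noise surrogate), plus
  optional blood-sample and parent-fraction noise;
* an in-vitro arm: per-animal autoradiogram plates (triplicate total and
  non-specific sections per region, co-exposed standards, a monotone cubic
  film response) whose true specific binding is proportional to the
  animal's regional true $V_t$, so the in vivo and in vitro endpoints share
  one inflammation signal.

What the generator deliberately does **not** emulate: image reconstruction
and its correlated noise, partial-volume effects, attenuation/scatter,
blood–brain-barrier perfusion changes, or TSPO binding-affinity
subpopulations. Passing tests therefore demonstrate correctness of the
quantification chain under the stated statistical structure, not robustness
to every artefact of real scanner data.

## Worked example

```{r example, eval = FALSE}
cfg <- default_cohort_config(
  regions = dplyr::filter(kase_region_table(), region == "amygdala")
)
report <- run_study(cfg, seed = 1)
report$vt_summary
report$correlations
autoplot(report)
```

## Problem sizes and determinism

The test-suite simulations use the sizes natural to the design: 8 animals
per cohort, the 28-frame schedule, 50-replicate recovery runs,
200-replicate percent-increase distributions and 1000-replicate type-I
calibrations. All randomness flows through explicit seeds
(`withr::with_seed`), so identical seed and configuration reproduce every
table and file byte-for-byte.

## Known limitations

* One-tissue model only: no two-tissue (4-parameter) variants, no
  reference-tissue models (none is valid for TSPO), no voxelwise maps.
* No delay/dispersion correction of the input function.
* r50′ inherits a clearance-dependent bias relative to $V_t$ (see above).
* The cross-isotope film response is captured only through the empirical
  standards curve.
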