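---
title: "Methods: simulating bioequivalence trials to probe absorption-rate metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating bioequivalence trials to probe absorption-rate metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Average bioequivalence compares a test (T) against a reference (R)
formulation on the extent of absorption — AUC, about which there is no
controversy — and on its *rate*, for which the maximum concentration Cmax
is the conventional surrogate. Cmax, however, has concentration units, not
rate units, and for most disposition settings it responds only weakly to a
genuine change in the absorption rate constant Ka. The average slope of
the ascending limb of the concentration-time curve,

$$AS = \frac{1}{n-1}\sum_{i=1}^{n-1}\frac{C_{i+1}-C_i}{t_{i+1}-t_i},$$

with $n$ the number of samples up to and including Tmax, and its weighted
variant

$$ASw = \frac{1}{n-1}\sum_{i=1}^{n-1}
  \frac{T_{max}-t_i}{T_{max}}\cdot\frac{C_{i+1}-C_i}{t_{i+1}-t_i},$$

carry true concentration/time units and are computable by strictly
non-compartmental means. `slopeBE` provides the machinery to quantify, by
simulation, how sensitively each candidate metric tracks absorption-rate
differences and what that sensitivity costs in statistical power.

## The simulation model

Three oral drugs with deliberately different absorption speeds are built
in as presets: hydrochlorothiazide (two-compartment disposition with a
24.24 min absorption lag, fast absorption), donepezil (one-compartment,
moderate), and amlodipine (one-compartment, slow). Their population
parameters and per-drug sampling schedules are stored in
`inst/extdata/drug_presets.yaml`; time is minutes throughout, volumes mL,
so concentrations are µg/mL.

Two corrections/choices deserve emphasis:

* The literature amlodipine central volume is printed as 1,300 mL, which
  would imply a terminal half-life of about 2.4 minutes — irreconcilable
  with the drug's well-documented 40–50 h. The default preset uses
  1,300 L, which yields 40.6 h; the literal value remains selectable
  (`drug_preset("amlodipine", amlodipine_v1 = "literature")`).
* Doses are not part of the published parameter sets. Defaults are the
  common label strengths (25/10/10 mg). Every quantity the package
  reports on the ratio scale (GMRs, acceptance rates, standardized PCA)
  is dose-invariant under these linear models, so the choice only fixes
  the concentration scale.

Profiles are produced from closed-form solutions — the Bateman equation
for one compartment, the tri-exponential solution in the disposition
eigenvalues for two compartments — and cross-checked against an adaptive
Runge–Kutta integration (`deSolve`, Dormand–Prince 4(5)) to within 0.1%
at every scheduled sampling time. The closed form switches to its
repeated-root limit when $|K_a - k_e|/K_a < 10^{-8}$, and the
two-compartment solution falls back to the integrator if its
eigenstructure degenerates; both guards exist for numerical stability,
not because the presets approach them.

## Virtual subjects and the variability model

A virtual trial draws, for each subject, every model parameter from a
lognormal distribution centred on the population value with
between-subject CV 10% ($\sigma^2=\log(1+cv^2)$); each period applies an
additional, independent within-subject perturbation (CV 10% by default,
with 5% and 20% as the explored low/high settings); and each observed
concentration receives proportional residual error,
$C_{obs}=C(1+\varepsilon)$. Subjects are randomized 1:1 to the TR and RT
sequences of a standard 2×2 crossover; the test formulation differs from
the reference only through Ka (KaT = ratio × KaR). Negative observed
concentrations are truncated to zero and the pre-dose sample stays
exactly zero.

The residual error magnitude is nowhere specified in the source
literature; the package default is 5%, chosen once as "small relative to
the 10% parameter-level CVs" so that parameter variability dominates.
Because within-subject variability is realized as per-occasion parameter
perturbation (one perturbation per subject-period) *plus* this residual
layer, the effective per-metric variance is a modelling decision, and
several power results are sensitive to it (see *Known limitations*).

What the generator does **not** emulate: dropout, missing samples,
quantification limits, period or carryover effects, nonlinear kinetics,
and absorption models beyond first-order-with-lag. Passing tests
therefore demonstrate internal statistical behaviour under an idealized
complete-data trial, not robustness to real bioanalytical artifacts.

## Non-compartmental estimation

`nca_metrics()` computes Cmax/Tmax (earliest-time tie-break), AUC by the
linear trapezoidal rule, $\lambda_z$ by log-linear regression on the last
$k \ge 3$ positive samples strictly after Tmax with $k$ chosen to
maximize adjusted $R^2$ (ties within $10^{-4}$ prefer more points; a
fixed-$k$ mode is available), AUCinf $= AUC + C_{last}/\lambda_z$, and
AS/ASw. Two conventions in AS/ASw were genuinely open and are fixed as
follows:

* the $t=0$, $C=0$ pre-dose sample **is** part of the point set (the
  first chord captures the initial rise; excluding it would blind AS to
  the fastest part of absorption);
* the ASw weight uses the interval's left endpoint $t_i$, exactly as the
  defining sum indexes it, so the final interval before Tmax carries a
  small positive weight.

Profiles whose observed maximum falls on the first sample leave AS
undefined; under trial analysis such subjects (and any subject with a
non-positive metric value, which extreme noise can produce for AS) are
excluded from that metric's ANOVA only, with a count reported — the
least intrusive standard handling of log-scale requirements.

## Trial statistics

Each metric is log-transformed and analyzed with the classical
fixed-effects 2×2 crossover ANOVA (sequence, subject within sequence,
period, formulation), giving the T−R effect, residual mean square, and
$df=n_1+n_2-2$. The 90% confidence interval of the geometric mean ratio
uses the usual $t$-based formula, and bioequivalence is declared when the
interval lies inside the closed acceptance interval (default 80–125%,
with 75–133% and 70–143% as widened presets). Tmax is computed but not
BE-tested. With zero variability and ratio 1 the machinery is exactly
calibrated: GMR = 1, degenerate CI, universal acceptance.

## Monte Carlo sweeps

`run_sweep()` repeats the whole pipeline `n_trials` times per KaT/KaR
grid point (default grid 1.0–2.0 by 0.1, default 10,000 trials) and
aggregates the mean GMR and percent acceptance per metric with Monte
Carlo standard errors. Seeding is counter-based: the master seed derives
one integer seed per (scenario, ratio, trial) below $2^{31}$, so runs are
bit-reproducible and any single trial can be replayed in isolation.
`scenario_matrix()` crosses sample sizes, within-subject variability
levels and limit sets. The reproduction analyses in this package use
N = 24 with 10% variabilities as the baseline; the test suite runs
250–2,000 trials per point and the acceptance script 1,000, sizes chosen
to keep Monte Carlo standard errors comfortably inside the tolerance
bands being checked (binomial SE ≤ 1.6 percentage points at 1,000
trials).

## PCA of the metric correlation structure

For the relationship analysis, 100 subjects are simulated at ratio 1, the
200 pooled T/R records' six metrics are z-standardized (population SD,
denominator $n$ — matching common scaler behaviour), and the matrix is
decomposed by SVD with all six components retained; explained variance
fractions are $s_k^2/\sum s^2$. The SVD's sign freedom is resolved by
orienting PC1 so Cmax loads positively and PC2 so AS loads negatively —
a display convention only; all reported pairwise vector angles are
invariant to it. "Rotation" here means exactly this axis-orientation
freedom; no varimax or oblique rotation is applied. Angles come from the
first two loadings per metric: the AS and Tmax vectors sit nearly
antiparallel (~150–160°), AUC/AUCinf nearly orthogonal to Tmax, and Cmax
between AS and AUC — the geometric signature of Cmax expressing extent
more than rate.

## Known limitations

* **Power baselines are variance-sensitive.** Mean-GMR (sensitivity)
  curves reproduce robustly, but percent-acceptance values at
  intermediate Ka ratios depend steeply on the per-metric residual MSE,
  which in turn depends on the unpublished residual-error magnitude and
  sample size behind the reference figures. Under this package's fixed
  baseline, some published acceptance percentages (notably
  hydrochlorothiazide at ratio 1.2) are not matched.
* **ASw variance on lagged, front-loaded schedules.** With left-endpoint
  weights, the early intervals of the hydrochlorothiazide schedule (which
  fall inside the absorption lag and carry zero slope) receive the
  largest weights while the noisy near-peak interval is down-weighted;
  ASw consequently shows *lower* trial-to-trial variance than AS and
  higher acceptance for this drug, whereas the reference analysis reports
  ASw as the least permissive metric. For donepezil (no lag, denser early
  sampling) the expected ordering emerges. This is a substantive
  consequence of the weighting definition worth knowing before adopting
  ASw for rapidly absorbed lagged drugs.
* **PCA explained variance inherits the noise model.** The first two
  components' share drops several points as residual error grows (for
  donepezil: ~90% at 0% error, ~82% at 5%, ~79% at 10%), so comparisons
  against published explained-variance figures carry that uncertainty.
* AS can be negative under extreme noise; the package returns it as
  computed and leaves the exclusion decision to the trial layer.
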