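---
title: "Methods: conditional-distribution dose individualization for sunitinib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional-distribution dose individualization for sunitinib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sunidose)
```

## The problem

Sunitinib exposure varies several-fold between patients on the same
nominal dose, and both its efficacy (VEGFR/PDGFR inhibition requires
total trough concentrations of roughly 50 ng/mL and above) and its
dose-limiting toxicities (more frequent above 100 ng/mL) track
exposure rather than dose. Therapeutic drug monitoring is practical —
a single plasma sample measuring sunitinib and its active metabolite
N-desethyl sunitinib — but samples are rarely drawn exactly at the
24 h trough. This package estimates each patient's individual PK from
whatever sample is available, simulates the steady-state trough and
AUC in silico, and searches a dose grid for the dose most likely to
put **total** (parent + metabolite) exposure inside a therapeutic
window.

## Structural PK model

Each analyte follows a two-compartment model with first-order oral
absorption, solved in closed form (`conc_single_dose()`). All
parameters are apparent (bioavailability absorbed): `ka` (1/h), `cl`
= CL/F (L/h), `v1`, `v2` (L), `q` (L/h). Doses are in mg and
concentrations in ng/mL; the mg-to-ng and L-to-mL conversions
collapse into a single factor of 1000 applied once in the closed
form.

Two modelling choices deserve comment:

* **Metabolite as an independently dosed system.** The metabolite is
  described by the same structure receiving the parent's nominal
  dose, with the formation fraction folded into its apparent
  clearance and volumes. This matches how the two analytes' reference
  population models were reported (separate models, shared
  framework) and avoids inventing a parent-to-metabolite transit
  model that was never published. Consequence: parent and metabolite
  parameters are statistically independent in both prior and
  posterior, and metabolite kinetics after a dose *change* are
  assumed to re-equilibrate exactly like a directly dosed compound.
  No absorption lag is used.
* **Steady state as the continuous once-daily limit.** Exposure
  metrics use the accumulation-factor form of the closed-form
  solution (each exponential multiplied by \(1/(1-e^{-\lambda\tau})\)).
  The 4/2 and 2/1 on/off cycles are carried on `dose_regimen` as
  metadata but do not perturb the steady-state metrics: TDM samples
  are drawn at least ten days into a cycle, far beyond the ~2–4 day
  accumulation horizon of the absorption phase but within the "on"
  period, where the infinite-train approximation is standard
  practice. A cycle-explicit simulation mode is deliberately out of
  scope.

Numerical details: the triexponential is singular when `ka` collides
with a hybrid disposition rate, so `ka` is perturbed by one part in
10⁶ whenever it comes within a relative 10⁻⁹ of α or β. Times after
dose larger than τ are allowed and interpreted as a delayed sample
with the next dose withheld — the accumulation formula remains exact
under that reading, and late (25–26 h) TDM samples are common. The
steady-state interval AUC uses the identity dose/CL rather than
quadrature.

## Population prior and likelihood

The prior is log-normal and diagonal: \(\theta_i =
\theta_{pop}e^{\eta_i}\), \(\eta_i \sim N(0,\omega^2)\) independently
per parameter. By default only the clearances and central volumes of
the two analytes carry variability (ω = 0.35/0.45 for the parent,
0.40/0.50 for the metabolite); absorption and distributional
parameters are fixed at their typical values, because sparse one-
sample TDM data cannot inform them and the reference analysis kept
its base model similarly lean. No IIV correlation structure is
supported — none was published.

The bundled typical values (`default_population()`,
`inst/extdata/sunitinib_population.yaml`) transcribe the base model
of the published sunitinib population-PK meta-analysis, with the
metabolite's parameters dose-referenced through its fixed formation
fraction (0.21). At 50 mg QD they give a typical total trough of
about 55 ng/mL and total AUC of about 1580 ng/mL·h — inside both
windows, as a typical patient on the registered dose should be.

Residual error is combined proportional + additive per analyte,
variance \(\sigma_{add}^2 + (\sigma_{prop} f)^2\) around the
prediction \(f\). The bundled magnitudes (σ_prop = 0.2, σ_add =
1 ng/mL) are working values for simulation and testing; the
underlying assay publishes a 10 ng/mL lower limit of quantification
but not an error model. Measurements below the LOQ enter the
likelihood as left-censored contributions \(\log \Phi((LOQ -
f)/\sigma)\) (the M3 convention) rather than being discarded or
substituted, preserving the information that a sample was low.
Patients with only one measured analyte are accepted; the likelihood
simply runs over the rows available.

## Conditional estimation

`sample_conditional()` targets the conditional (posterior)
distribution of the free parameters given the observations, using
random-walk Metropolis–Hastings on the log-parameters, where the
prior is exactly Gaussian. The proposal is diagonal with
per-parameter scale proportional to ω times a global factor started
at \(2.38/\sqrt{k}\) and adapted in batches of 50 iterations during
burn-in toward a 20–40% acceptance rate, then frozen so the chain is
a valid fixed-kernel sampler afterwards. Defaults: 1000 burn-in
iterations, 1000 retained draws, no thinning; all three are
arguments, and prior-recovery checks (which compare against i.i.d.
prior draws) use thinning 10 to suppress autocorrelation. Runs are
bit-reproducible given the seed, and the sampler restores the
caller's RNG state, so estimation never perturbs an enclosing
simulation.

`map_estimate()` is the classical empirical Bayes mode, provided as
a comparison baseline: it maximizes the *natural-scale* posterior
density over the log-parameters (multi-start BFGS). The distinction
matters — the natural-scale prior mode is \(\theta_{pop}
e^{-\omega^2}\), not \(\theta_{pop}\); the MCMC target and the MAP
objective therefore differ by the Jacobian \(\sum_j \theta_j\), which
is intentional and covered by tests. Overflow of \(e^\theta\) during
optimization or sampling is mapped to a −∞ posterior rather than an
error.

`virtual_trough()` pushes every retained draw through the
steady-state model and reports the median (the point estimate —
robust to the right-skewed exposure distribution), mean, and 5th/95th
percentiles of the total trough.

## Dose recommendation

`recommend_dose()` scores each grid dose by the fraction of draws
whose total trough (or AUC) lies inside the window, bounds inclusive.
Because the PK is linear, the metric at dose *d* is exactly
\(d/d_0\) times the metric at the reference dose — the grid search
is a deterministic rescaling, and tests assert *equality* with this
oracle, not approximation.

Policy choices, all configurable:

* **Grid** 12.5–100 mg in 12.5 mg steps. The lower bound is 12.5
  rather than 25 because −75% recommendations (50 → 12.5 mg) occur
  in practice for heavily overexposed patients.
* **Ties** within 1/n of the maximal fraction break toward the
  lowest dose (toxicity minimization); a zero-fraction dose never
  ties with a positive maximum.
* **Unreachable window**: when no grid dose attains the window at
  all, the recommendation is the grid dose minimizing the expected
  squared distance of the metric to the window midpoint, flagged
  `window_unreachable`, with the tie-broken argmax also reported.
  For a patient measured at a 13 ng/mL trough on 50 mg this rule
  recommends the grid maximum (100 mg), matching how a
  target-seeking engine behaves for severely underexposed patients;
  pure fraction-argmax would absurdly suggest 12.5 mg.
* **Action** is `keep` iff the recommended dose equals the current
  dose exactly; otherwise the sign decides. Window bounds: trough
  50–100 ng/mL; AUC 1200–2150 ng/mL·h. (Published sources disagree
  between 1200 and 1250 for the AUC floor; 1200 — the Methods-level
  value — is the default, and the bound is a plain argument.)

## Synthetic cohort generator

`generate_cohort()` is the package's testbed: it draws true
individual parameters from the prior, assigns initial regimens from
the observed real-world mix (80.7% at 50 mg, 9.7% at 37.5, 6.4% at
62.5, 3.2% at 12.5; 93.6% on 4/2), draws one steady-state sampling
time per patient uniformly on 2–26 h with a 20% point mass exactly at
24 h (about a fifth of real TDM samples are true troughs), simulates
both analytes with residual error and LOQ censoring, and generates
toxicity / benefit labels from logistic models on log total AUC. The
default outcome coefficients produce a weak positive
exposure–toxicity gradient and a weaker exposure–benefit one — trends
of the size that fail significance at n ≈ 31 — so that the analytics
layer can be validated against a known ground truth.
`apply_empirical_rules()` emulates clinical-sign-based tailoring
(reduce toxic patients' dose with probability 0.41 by a 25% step;
increase non-benefiting patients' dose with probability 0.18).

What the generator does **not** emulate: covariate effects (body
size, ABCG2 genotype), adherence lapses, inter-occasion variability,
parent–metabolite correlation, longitudinal dose-titration
trajectories, dropout, or model misspecification — every virtual
patient is generated by the same structural model the estimator
assumes. Passing recovery tests therefore demonstrates the
correctness of the inferential machinery, not the adequacy of the
two-compartment model for real patients.

## Test problem sizes and numerical tolerances

The suite checks the closed form against adaptive ODE integration
(10⁻⁶ relative, 100 random parameter sets), superposition over 200
doses (0.01%), the Bateman one-compartment limit at q = 10⁻⁸
(0.01%), the AUC identity to machine precision, prior recovery by
two-sample Kolmogorov–Smirnov at 2000 draws, MAP against exhaustive
400 × 400 log-grid search, clearance recovery within 15% from a
low-noise sample pair, exact equality of grid fractions with the
linear-scaling oracle, and a full 200-patient simulate → estimate →
recommend → analyze pipeline (two samples per patient, 400–500 MCMC
draws per patient) with median clearance error under 25% and
attainment-classification agreement of at least 70% between true and
estimated exposure. Type-I error of the exposure association test is
calibrated on 500 replicate null cohorts of 60 patients (rejection
rate 5% ± 2%). These sizes were chosen as the smallest that make the
statistical assertions stable across seeds.

## Known limitations

* The conditional sampler is a single-chain random-walk sampler;
  for the 2–4 dimensional, unimodal posteriors arising from sparse
  TDM data this is ample, but it is not a general-purpose NLME
  engine and performs no population fitting.
* Dose recommendations assume linear (dose-proportional) PK across
  the whole 12.5–100 mg grid.
* The metabolite independence assumption ignores the correlation
  between parent and metabolite exposure induced by shared
  absorption and conversion; with both analytes measured at a shared
  time this mostly affects extrapolation, not interpolation.
* Schedule switching (4/2 versus 2/1) and toxicity-adjusted utility
  scoring are out of scope; recommendations act on the dose only.
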