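# sunidose

Model-informed precision dosing (MIPD) for sunitinib in metastatic renal
cell carcinoma, from sparse therapeutic drug monitoring (TDM) samples.

Sunitinib is dosed at 50 mg once daily (4 weeks on / 2 weeks off) almost
regardless of the 40–50% inter-patient variability in its exposure, and
dose changes in routine care are usually driven by clinical signs —
reducing after toxicity appears, increasing when efficacy seems lacking.
`sunidose` implements the model-based alternative: estimate each
patient's individual pharmacokinetic (PK) parameters from a single
plasma sample drawn at any time post-dose, simulate their steady-state
exposure, and pick the dose that best places them inside a therapeutic
window for **total sunitinib** (parent + active metabolite N-desethyl
sunitinib): trough concentration 50–100 ng/mL, or AUC over the dosing
interval 1200–2150 ng/mL·h. It is written for pharmacometricians and
clinical-pharmacology researchers studying TDM-guided dose
individualization.

## The model

Both analytes follow a two-compartment disposition model with
first-order oral absorption (all parameters apparent, i.e. scaled by
bioavailability; the metabolite receives the parent's nominal dose with
its formation fraction absorbed into its apparent clearance and
volumes). The plasma concentration after one dose D is the standard
triexponential

C(t) = (D·ka/V₁) · [A·e^(−αt) + B·e^(−βt) + C·e^(−ka·t)],

with hybrid rate constants α, β given by α+β = (CL+Q)/V₁ + Q/V₂ and
α·β = CL·Q/(V₁·V₂). At steady state under once-daily dosing each
exponential acquires its accumulation factor 1/(1−e^(−λτ)); the trough
is C_ss(τ) and the interval AUC is D/CL exactly.

Individual parameters are estimated in the Bayesian framework used in
population PK: a log-normal prior θᵢ = θ_pop·e^η, η ~ N(0, ω²), and a
combined proportional + additive residual error with left-censored
(M3) handling of samples below the 10 ng/mL quantification limit.
Rather than stopping at the most probable value (the empirical Bayes
estimate, which is also available via `map_estimate()`), the package
samples the full **conditional distribution** of the parameters given
the measured parent and metabolite concentrations, by adaptive
random-walk Metropolis–Hastings on the log-parameters. Each candidate
dose on a 12.5–100 mg grid is then scored by the *fraction of
conditional-distribution exposure profiles inside the therapeutic
window*, and the best dose (ties broken toward the lower dose) is
recommended. When no dose can reach the window, the dose bringing the
expected exposure closest to the window midpoint is recommended
instead, with a flag.

The bundled population prior (`default_population()`) transcribes the
base model of the published sunitinib population-PK meta-analysis for
both analytes; see `inst/extdata/sunitinib_population.yaml` for values,
units and provenance notes.

## Worked example

A patient on 50 mg QD was sampled at steady state 24 h post-dose:
parent 30 ng/mL, metabolite 13 ng/mL (total 43 ng/mL — below the
50–100 ng/mL target).

```r
library(sunidose)
pop  <- default_population()
recs <- read_patient_records(sunidose_example("synthetic_underexposed_records.csv"))
rec  <- recs[["2"]]

draws <- sample_conditional(pop, rec$observations, rec$regimen,
                            n_draws = 1000, seed = 42)
virtual_trough(draws, rec$regimen)$median
#> [1] 44.68   # in-silico T24h trough, ng/mL

recommend_dose(draws, rec$regimen, window = therapeutic_window("trough"))
#> <dose_recommendation> increase: 50 mg -> 75 mg (+50.0%)
#>   dose fraction_in_window
#>   12.5              0.000
#>   25.0              0.000
#>   37.5              0.002
#>   50.0              0.175
#>   62.5              0.853
#>   75.0              0.991
#>  100.0              0.825
```

Staying at 50 mg leaves only 17.5% of the patient's plausible exposure
profiles inside the window; 75 mg maximizes that fraction at 99.1%, so
the model recommends a dose increase — the same action class a
measured-trough engine proposes for such underexposed patients.

The same machinery runs from a shell:

```sh
Rscript inst/cli/sunidose recommend \
  --records records.csv --window trough --seed 2 --out results/
```

with subcommands `simulate-cohort`, `estimate`, `recommend`, `analyze`
and `report`.

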