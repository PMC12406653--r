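---
title: "Model-based tobramycin dosing in children: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based tobramycin dosing in children: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tobradose)
```

## The problem

Once-daily intravenous tobramycin for pulmonary exacerbations in children
with cystic fibrosis is conventionally dosed at a flat 10 mg/kg. Tobramycin
is cleared almost exclusively by glomerular filtration, which changes with
body size, renal maturation and renal function — none of which a flat mg/kg
rule tracks. The accepted exposure target is a steady-state 24-hour area
under the concentration-time curve (AUC~24,ss~) of 80–110 mg·h/L: below it
bacterial killing is compromised, above it nephro- and ototoxicity risk
rises. This package implements the full model-based alternative: predict a
child's clearance from covariates, pick the daily dose that puts the
*predicted* exposure on target, and quantify — by simulation — how often the
*realized* exposure lands in the window.

## The structural and covariate model

Serum concentrations follow a one-compartment model with zero-order infusion
and first-order elimination, parameterized by clearance CL (L/h), volume V
(L) and infusion duration D1 (h). D1 is a model parameter rather than a
constant because documented infusion times in routine care are imprecise;
prospective simulation uses the nominal 0.5 h while estimation-oriented
simulation uses the fitted typical value (0.801 h). At steady state with
once-daily dosing, exposure reduces to the identity AUC~24,ss~ = dose/CL,
which the package uses directly wherever only exposure matters.

Typical (population-predicted) values are

$$\mathrm{CL} = 6.17 \cdot
  \frac{\mathrm{PMA}^{3.4}}{47.7^{3.4} + \mathrm{PMA}^{3.4}} \cdot
  \left(\frac{\mathrm{WT}}{70}\right)^{0.663} \cdot
  \left(\frac{\mathrm{eGFR}}{127.3}\right)^{0.4}, \qquad
  \mathrm{V} = 15.5 \cdot \left(\frac{\mathrm{WT}}{70}\right)^{0.744},$$

with PMA the postmenstrual age in weeks (52·age + gestational age, default
40 weeks at term), WT the weight in kg, and eGFR the modified Schwartz
estimate 41.3·height(m)/creatinine(mg/dL) in mL/min. The maturation term is
a Hill function reaching half its asymptote at 47.7 weeks PMA — renal
filtration approaches adult capacity around age two. The eGFR exponent is
fixed at 0.4 and not re-estimated by default. Creatinine units are a
mandatory declaration (`"umol/L"` or `"mg/dL"`, conversion factor 88.4);
silent unit guessing is a classic dosing-calculator failure mode and is
refused outright.

Between-subject variability is lognormal and diagonal:
parameter~i~ = typical·exp(η), η ~ N(0, ω²) with ω = 0.170 (CL), 0.173 (V)
and 0.404 (D1). The ω values are standard deviations on the log scale, the
standard pharmacometric reading of a "between-subject variability (standard
deviation)" table. Residual error combines additive (0.173 mg/L) and
proportional (10.3%) components: y = f·(1+ε~prop~) + ε~add~.

## Dosing rules

The individualized rule inverts the exposure identity at a target of
95 mg·h/L: dose = 95·CL~typical~, capped at the lower of 850 mg and
16 mg/kg (institutional limits); the binding cap is recorded in every
recommendation. The standard arm is 10 mg/kg, uncapped, mirroring how the
flat regimen is actually specified. Doses are not rounded by default (the
analysis works with fractional mg/kg); a 10-mg rounding flag exists for
clinical display. The theoretical-best analysis uses a target of 93.8
mg·h/L — numerically the geometric mean of the window bounds, which is the
exposure that equalizes the log-scale distance to both edges and hence
maximizes attainment under lognormal spread; the deployed rule's 95 is kept
as a separate configurable constant rather than silently unified.

## Probability of target attainment

Since dose = target·CL~typical~ cancels the typical clearance in
AUC = dose/CL~typical~·exp(−η), realized exposure under individualized
dosing (absent caps) is target·exp(−η) regardless of covariates. PTA then
has a closed form, Φ(ln(target/80)/ω) − Φ(ln(target/110)/ω) ≈ 0.65 at
ω = 0.170: this is the attainment *ceiling* of any covariate-based rule and
every Monte-Carlo run is cross-checked against it. Three design choices
matter:

* only η~CL~ enters the PTA classification — volume and infusion-duration
  variability leave steady-state AUC unchanged, and residual (assay) error
  is excluded because the target concerns true exposure, not a measured
  concentration;
* all arms are evaluated on the same virtual patients with the same
  clearance random effects (common random numbers), so arm contrasts are
  paired;
* pooled "all ages" results weight the three strata equally (1,000 virtual
  patients each, age strata <2, 2–12 and >12 years with age 12 in the
  middle group), mirroring the equal-allocation simulation design rather
  than any demographic age distribution.

## The synthetic cohort generator

No public covariate database exists for this population, so virtual
patients are generated rather than resampled: age uniform within stratum
(0.1–19.3 years overall); height and weight lognormally dispersed around
sex-pooled growth-reference medians (WHO-style under 2, CDC-style above),
with CV 4% for height and 12% for weight and weight partially tracking
height (∝ height², plus residual spread); serum creatinine lognormal around
an age-rising normal median (≈18 µmol/L in infancy to ≈56 µmol/L in late
adolescence, values consistent with a Schwartz eGFR centered near 120
mL/min in healthy children), CV 15%, truncated to 0.6–1.6× the age median
to keep every virtual patient "renally normal". Gestational age is fixed at
term. These references were chosen once, on plausibility grounds, and the
acceptance checks carry the tolerance that choice implies.

What the generator does *not* emulate: the real covariate correlations of a
CF clinic population (CF children tend to be lighter for age), disease
progression, sex effects, or abnormal renal function. Consequently the
standard-arm PTA — which depends on the joint distribution of weight-for-age
and eGFR — reproduces the reference analysis only approximately (pooled
≈0.36 versus 0.31 reported from the private 704-child database; <2 years
≈21% versus 15%), while individualized-arm PTA, which is covariate-robust by
the cancellation argument above, lands on the reported values almost
exactly. Passing simulations therefore validate the *method*, not the
demographic detail of any particular clinic.

For estimation validation (parameter recovery, covariate selection) the
cohorts use a wider creatinine spread (CV 0.35, band 0.35–2.6× the median),
emulating a clinical TDM population with eGFR spanning roughly 50–270
mL/min. This is deliberate: with the normal-band spread of the PTA cohort,
the eGFR effect (exponent 0.4 on a covariate whose log-SD is ≈0.16) is
smaller than what n = 63 subjects can reliably detect, and no estimator
could meet a 90% selection-power contract; with a clinically realistic
spread the effect is comfortably detectable. TDM sampling follows routine
practice: one draw 1–2 h and one 4–8 h after the start of the infusion on
monitored doses (defaults: doses 1, 3 and 5 of a 7-day course), with
observations below the 0.6 mg/L quantification limit censored.

## Estimation

The mixed-effects model is estimated by per-subject Laplace approximation:
for each subject the three random effects are set to the mode of their
conditional (penalized) objective and the marginal integral is approximated
by a second-order expansion there, giving an objective function value (OFV)
on the −2·log-likelihood scale, constants included. The residual variance
g = σ²~add~ + (σ~prop~·f)² is evaluated at the conditional prediction, so
the proportional-error "interaction" is retained. With all ω = 0 the OFV
reduces exactly to the weighted least-squares deviance
Σ[(y−f)²/g + ln g] + n·ln 2π, which is the hand-checkable anchor used in
the tests. Exact replication of any specific estimator implementation is a
non-goal; recovery of the generating parameters is the contract.

Numerical design:

* the inner (conditional-mode) optimization runs in compiled code as a
  damped Newton search with finite differences. The inner objective is
  genuinely multimodal in η~D1~ — moving the end-of-infusion kink across an
  observation time creates distinct local minima — so the search is
  multi-started (warm start from the previous outer iteration, the prior
  mean, and η~D1~ = ±0.75) and keeps the best mode. Residual
  evaluation-to-evaluation hysteresis is below 0.2 OFV units, well under
  the 3.84 decision threshold;
* the outer optimization (`nlminb`) works on log-transformed scale and
  variance parameters, enforcing positivity by construction; covariate
  coefficients are unconstrained;
* a "false convergence" report caused by sub-tolerance inner hysteresis is
  accepted only after an explicit flatness check (finite-difference
  gradient scaled far below the LRT threshold); anything else is surfaced
  as a warning with partial estimates.

Observations below the quantification limit use the M6 convention: within
each dose interval the first of a consecutive run of BLQ records is
retained, imputed at half the limit (0.3 mg/L); later records of the run
are discarded; a quantifiable observation terminates the run, so a later
BLQ in the same interval starts a new run. A record exactly at the limit is
quantifiable (strict "<"). The rule is verified against a independent
enumeration over all flag patterns.

Covariate inclusion follows forward stepwise selection on the
likelihood-ratio scale: a candidate is retained when it drops the OFV by
strictly more than 3.84 (χ², 1 df, 5%); the largest significant drop wins
each round and every tested step is recorded in an audit trail. Failed
candidate fits are logged and skipped, never silently dropped.

## Problem sizes and reproducibility

The shipped validation suite simulates 1,000 virtual patients per age
stratum for attainment runs, 10⁵ draws for Monte-Carlo/closed-form
cross-checks, and 20 replicate TDM studies of 63 subjects (≈6 observations
each) for parameter recovery and selection operating characteristics —
sizes chosen to keep Monte-Carlo error visibly below the decision
tolerances while remaining comfortable on a single CPU. Every stochastic
stage draws from a named substream derived from one global seed
(`substream_seed()`), so adding a stage never perturbs another, and any run
is reproducible from `(config, seed)`; configurations round-trip through
YAML/JSON with a content hash for logging.

## Known limitations

* The synthetic cohort approximates a general pediatric population, not a
  CF clinic; standard-arm attainment inherits that approximation.
* D1 (infusion duration) is weakly identified by the routine TDM design —
  both samples usually fall after the infusion ends — so its typical value
  and variability recover with wide spread. Clearance and volume, the
  parameters that matter for dosing, are unaffected.
* The omega matrix is diagonal; no inter-occasion variability is modelled.
* Two-compartment kinetics, nonlinear elimination and non-IV routes are out
  of scope, as are MIC-indexed targets (the AUC window stands in for
  AUC/MIC).

## A worked example

```{r example}
child <- patient_covariates(age = 1, weight = 10, height = 0.75,
                            creatinine = 20, creatinine_unit = "umol/L")
cl <- typical_cl(child)
cl
optimal_dose(cl, weight = 10)
```

A one-year-old, 10 kg, 75 cm, creatinine 20 µmol/L: predicted clearance
1.58 L/h, recommended dose 150 mg (15 mg/kg — close to the 16 mg/kg cap,
as expected for infants, whose weight-normalized clearance is high).

```{r pta}
res <- run_pta(config = sim_config(n_per_group = 500, seed = 20251001))
subset(res$summary, stratum == "all",
       c(arm, frac_below, frac_within, frac_above))
```
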