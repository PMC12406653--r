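# tobradose

Model-based once-daily tobramycin dosing for children with cystic fibrosis,
and the population-pharmacokinetic machinery behind it. The package is aimed
at pharmacometricians and antimicrobial-stewardship researchers who want to
(i) predict a child's tobramycin clearance from routine covariates,
(ii) choose the daily dose that targets a steady-state exposure
(AUC<sub>24,ss</sub>) of 95 mg·h/L under institutional caps,
(iii) quantify by Monte-Carlo simulation how often standard (10 mg/kg) versus
individualized dosing attains the 80–110 mg·h/L therapeutic window, and
(iv) re-estimate the underlying nonlinear mixed-effects model from
therapeutic-drug-monitoring (TDM) data, including censored observations.

## The model

Serum kinetics are one-compartment with zero-order infusion and first-order
elimination. Typical clearance and volume come from an allometric +
maturation + renal-function covariate model:

    CL (L/h) = 6.17 · PMA^3.4 / (47.7^3.4 + PMA^3.4) · (WT/70)^0.663 · (eGFR/127.3)^0.4
    V  (L)   = 15.5 · (WT/70)^0.744

with PMA the postmenstrual age in weeks (52·age + gestational age, 40 if
unknown), WT in kg, and eGFR the modified Schwartz estimate
41.3·HT(m)/CR(mg/dL). Between-subject variability is lognormal
(ω<sub>CL</sub> = 0.170, ω<sub>V</sub> = 0.173, ω<sub>D1</sub> = 0.404);
residual error is additive + proportional (0.173 mg/L, 10.3 %). At steady
state AUC<sub>24,ss</sub> = dose/CL, so the individualized rule is simply

    dose (mg) = 95 · CL,   capped at min(850 mg, 16 mg/kg).

Because that dose cancels the typical clearance, realized exposure is
95·exp(−η) and the attainment of 80–110 mg·h/L has a normal-CDF closed form
(≈ 0.65 at ω = 0.170) — the ceiling any covariate-based rule can reach,
against which all simulations are cross-checked.

## Worked example

```r
library(tobradose)

child <- patient_covariates(age = 1, weight = 10, height = 0.75,
                            creatinine = 20, creatinine_unit = "umol/L")
(cl <- typical_cl(child))
#> [1] 1.579108
optimal_dose(cl, weight = 10)
#>       dose dose_perkg cap_applied predicted_auc
#> 1 150.0153   15.00153        none            95
```

A one-year-old (10 kg, 75 cm, creatinine 20 µmol/L) has a predicted
clearance of 1.58 L/h; the AUC-targeted dose is 150 mg once daily
(15 mg/kg — infants need far more than 10 mg/kg by weight because their
weight-normalized clearance is high), predicted exposure exactly on the
95 mg·h/L target. The same computation is available from a shell via the
thin wrapper in `inst/cli/`:

```sh
Rscript inst/cli/tobradose.R dose --age 1 --weight 10 --height 0.75 \
    --creatinine 20 --creatinine-unit umol/L
```

Simulating attainment for 1,000 virtual patients per age stratum:

```r
res <- run_pta(config = sim_config(n_per_group = 1000, seed = 20251001))
subset(res$summary, stratum == "all", c(arm, frac_below, frac_within, frac_above))
#>                 arm frac_below frac_within frac_above
#> 4          standard      0.444       0.376      0.180
#> 8    individualized      0.159       0.652      0.189
#> 12 theoretical-best      0.177       0.653      0.170
```

Standard 10 mg/kg dosing leaves ~44 % of simulated children below the
window (mostly the youngest) while individualized dosing reaches the
theoretical ceiling of ~0.65 — the residual misses are irreducible
between-subject variability, not dosing error.

The estimation side consumes NONMEM-style CSV datasets (`read_pk_dataset()`,
`simulate_tdm()`), applies the M6 rule to below-quantification records
(`preprocess_m6()`), fits the mixed-effects model by Laplace approximation
(`fit_poppk()`), and runs forward likelihood-ratio covariate selection
(`forward_selection()`), each exposed as both functions and CLI subcommands.

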