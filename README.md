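# cvdcompare

Tools for comparing 10-year cardiovascular disease (CVD) risk prediction
models on a participant-level cohort, aimed at epidemiologists studying how
model choice changes who is called high-risk — and who is recommended a
statin — in populations the models were never derived on.

Six widely used risk equations are shipped as declarative, human-auditable
coefficient configurations and evaluated through one shared engine:

| model id | functional form | metabolic input |
|---|---|---|
| `pce` | Cox baseline-survival, sex x ancestry strata | lipids |
| `apce` | logistic (revised equations refit on updated cohorts) | lipids |
| `framingham_lipids` | Cox baseline-survival, sex strata | lipids |
| `framingham_bmi` | Cox baseline-survival, sex strata | BMI |
| `who_lipids` | Cox baseline-survival, sex strata (synthetic coefficients) | lipids (mmol/L) |
| `who_bmi` | Cox baseline-survival, sex strata (synthetic coefficients) | BMI |

Cox-form models compute `p = 1 - S0 ^ exp(LP - c)` where `LP = sum_k beta_k
f_k(x)` is the linear predictor over transformed covariates, `S0` the
baseline 10-year survival, and `c` the centering constant; the logistic model
computes `p = 1 / (1 + exp(-LP))`. Coefficients live in YAML files under
`inst/extdata/models/`, each carrying a source citation and a transcription
checksum — equations are data, not code. The two WHO-style configs are
clearly labelled **synthetic** stand-ins in the WHO functional form (the
original region-calibrated coefficient tables were not available for
transcription); they exercise the pipeline but are not for clinical use.

On top of the engine the package provides:

- **Cohort preparation**: seated-BP averaging (readings 2 and 3), the
  analytic-sample exclusion cascade (incomplete data, age < 40, statin use,
  prior MI/stroke) with first-failure attribution, and derived
  hypertension/treated-SBP covariates.
- **Categorization**: low/intermediate/high under a uniform scheme
  (5% / 7.5%) and under model-specific thresholds (PCE-type 5%/7.5%,
  Framingham 10%/20%, WHO 5%/20%), plus low-vs-high discordance patterns.
- **Statin eligibility**: the three rule families (PCE-type LDL/diabetes/risk
  ladder; the five-criterion Framingham ladder with risk-factor counting;
  the WHO 20% threshold).
- **Comparison statistics**: Spearman rank concordance matrices, Pearson
  chi-square tests of independence, Wilson score intervals, and high-risk
  risk-factor profiles.
- **Synthetic cohorts**: a seeded Gaussian-copula generator whose default
  marginals (`inst/extdata/haiti_table1.yaml`) emulate an urban Haitian
  adult cohort (60.9% female, median age 54, 52.9% hypertension, 7.8%
  diabetes, 4.0% smoking, ...), so the full pipeline runs without access to
  restricted participant data.

## Worked example

```r
library(cvdcompare)

cohort <- generate_cohort(cohort_marginals(), n = 1345, seed = 7)
res    <- run_pipeline(run_config(simulate_n = 1345, seed = 7))

# median predicted 10-year risk per model (percent)
aggregate(risk10y ~ model_id, res$scores, function(x) round(100 * median(x), 1))
#>            model_id risk10y
#> 1              apce     3.8
#> 2    framingham_bmi     9.8
#> 3 framingham_lipids     8.6
#> 4               pce     6.1
#> 5           who_bmi     4.2
#> 6        who_lipids     4.4

print(res$comparisons$model_specific$spearman["pce", "apce"])
#> 0.977
res$comparisons$model_specific$n_discordant
#> 147
```

The spread — a median of 3.8% under the revised logistic equations versus
9.8% under the office-based Framingham model, with 147 of 1345 simulated
adults called low-risk by one model and high-risk by another — is the
phenomenon the package is built to quantify: model choice, not patient
physiology, drives much of who gets flagged for primary prevention.

A thin CLI over the same pipeline is available as
`Rscript scripts/cvd_pipeline.R --simulate --n 1000 --seed 7 --out run1`.

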