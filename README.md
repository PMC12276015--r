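# haebn

Discrete Bayesian-network analysis of in-hospital mortality risk for
hereditary angioedema (HAE) admissions.

HAE (ICD-10 D84.1) is a rare genetic disorder — C1-esterase-inhibitor
deficiency causing recurrent swelling attacks, including
life-threatening laryngeal edema. Hospitalized HAE patients are few
(hundreds per year in national inpatient samples), so risk modelling
has to work in a small-sample, sparse-stratum regime. This package is
for epidemiologists and health-services researchers who want to model
how demographics (age group, race, income quartile, payer, census
region), comorbidities (hypertension, autoimmune disease, diabetes)
and APR-DRG admission severity propagate into a binary mortality-risk
outcome — and who need the whole pipeline to run without access to
licensed discharge data.

## The model

A discrete Bayesian network over 10 categorical nodes factorizes the
joint distribution along an expert-specified DAG:

        P(x₁, …, x₁₀) = ∏ᵢ P(xᵢ | pa(xᵢ))

Each node carries a conditional probability table (CPT). CPTs are
estimated from a cohort by Bayesian updating under a symmetric
Dirichlet prior: with per-category concentration α, the posterior mean
for category *k* under parent configuration *j* is

        θ̂ᵢⱼₖ = (Nᵢⱼₖ + α) / (Nᵢⱼ + kᵢ·α)

α = 1 (the default, a uniform prior) smooths the zero-count cells that
a cohort of a few hundred records inevitably leaves in fine strata.
Queries are answered by exact inference — variable elimination, backed
by a full-joint enumeration oracle (65,536 states for the default
schema) — under **hard** evidence (a node fixed to a state) or **soft**
evidence (a Pearl virtual-evidence likelihood vector, so conditioned
nodes are observed probabilistically rather than pinned). On top of
the engine sit the analysis battery (baseline risk, per-state
conditioning deltas, multi-factor scenarios) and a validation stage
(stratified 70/30 split, eight-metric confusion panel, ROC/AUC in
probability and label form).

Because the inpatient database the schema mirrors is licensed, the
package ships a **calibrated synthetic generator**: a ground-truth
network whose exact marginals match the published cohort frequencies
(58% White, 48% hypertension, 21% diabetes, 40% private insurance,
38.7% high mortality risk, …) with monotone log-odds dependencies, so
fitting, inference and validation are exercised on realistic data.

## Worked example

```r
library(haebn)

truth  <- default_ground_truth()            # calibrated simulation truth
cohort <- sample_cohort(truth, n = 5000, seed = 2024)
bn     <- fit_network(cohort, truth$dag, alpha = 1)

round(100 * baseline_risk(bn), 1)
#> [1] 44.1

head(single_factor_deltas(bn), 5)
#>       node    state p_high delta_pp
#> 1 Severity  extreme  0.552    11.17
#> 2 Severity    minor  0.355    -8.57
#> 3 Severity moderate  0.383    -5.72
#> 4 Severity    major  0.497     5.62
#> 5 Autoimmune    yes  0.489     4.84

run_scenarios(bn)                           # soft evidence, strength 0.9
#>                         label mode p_high delta_pp
#> 1              Black, Midwest soft  0.492    5.185
#> 2                Black, South soft  0.442    0.141
#> 3    Black, Midwest, age >=65 soft  0.528    8.711
#> 4 Hispanic, Medicare/Medicaid soft  0.466    2.562

validate_pipeline(cohort, truth$dag, seed = 2024)
#> BN validation: 3500 train / 1500 test records
#>  train: acc 0.84 | bal.acc 0.84 | sens 0.83 | spec 0.85 | AUC 0.92 (prob) 0.84 (label)
#>  test:  acc 0.56 | bal.acc 0.58 | sens 0.66 | spec 0.50 | AUC 0.61 (prob) 0.58 (label)
```

Reading the output: the fitted model's no-evidence baseline (44.1%)
sits above the generator's true prevalence (38.7%) because the uniform
prior pulls the outcome's many sparse strata toward 0.5 — the
model-baseline-versus-raw-prevalence gap that small smoothed networks
exhibit by design. The delta table ranks states by how far hard
conditioning moves the high-risk posterior (admission severity
dominates, autoimmune disease is the strongest comorbidity), the
scenario table answers compound what-if queries under soft evidence,
and the validation panel shows the train/test generalization gap of a
discrete classifier (label-mode ROC curves are straight lines, so that
AUC is exactly (sensitivity + specificity)/2).

One call reproduces everything, writing the cohort, fitted network,
reports, validation JSON and a seed-stamped log:

```r
run_pipeline("results/run1", n = 441, cohort_seed = 1, split_seed = 1)
```

or from a shell via the thin wrapper
`inst/cli/bn_pipeline.R` (`simulate` and `run-all` subcommands).

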