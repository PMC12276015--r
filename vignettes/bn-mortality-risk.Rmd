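---
title: "Modelling mortality risk in hospitalized hereditary angioedema patients with a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mortality risk in hospitalized hereditary angioedema patients with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haebn)
```

## The problem and the model

Hereditary angioedema (HAE) admissions are rare enough that a national
inpatient sample yields only a few hundred records a year, yet the
clinical question — which demographics and comorbidities mark a
patient as high risk at admission — involves ten interacting
categorical dimensions. A discrete Bayesian network is a natural fit:
it factorizes the joint distribution of age group, race, income
quartile, payer, census region, hypertension, autoimmune disease,
diabetes, APR-DRG severity and a binary mortality-risk outcome along a
directed acyclic graph, so every quantity of interest is an exact
conditional probability rather than a regression coefficient.

The structure is expert-specified, not learned from data: the shipped
default routes the five demographic nodes directly into mortality
risk, age additionally into the three comorbidities, the comorbidities
into admission severity, and severity into mortality risk. The edge
set lives in a JSON config
(`system.file("extdata", "default_model.json", package = "haebn")`)
that is the single source of truth, so an alternative structure — for
example one where comorbidities reach the outcome only through
severity — is a config edit, not a code change. Arrows encode
statistical dependence, not causation, and the package deliberately
offers no do-calculus.

```{r}
dag <- default_model()
dag
```

## Parameter estimation and the prior

Each node's conditional probability table (CPT) is estimated as the
posterior mean under a symmetric Dirichlet prior with per-category
concentration `alpha`:

$$\hat\theta_{ijk} = \frac{N_{ijk} + \alpha}{N_{ij} + k_i\,\alpha}$$

`alpha = 1` is the default: a uniform prior that doubles as add-one
smoothing, so no probability is ever exactly 0 or 1 and unobserved
parent configurations fall back to the uniform vector. This matters at
study scale — with 441 records, the outcome node's table (six parents,
4096 rows) is almost entirely unobserved. We report the posterior
*mean*, not the MAP mode; users expecting the mode should note the two
coincide only asymptotically. `alpha` is exposed because the smoothing
strength is a genuine modelling choice: `alpha = 0` (maximum
likelihood) is allowed only when every stratum is observed, and tiny
values such as `1e-3` approximate the MLE while retaining full
support.

A consequence worth stating plainly: the fitted network's no-evidence
baseline `P(high)` is pulled from the raw prevalence toward 0.5 by
whatever prior mass the sparse outcome rows retain. At n = 441 under
`alpha = 1` this pull is large (roughly +10 percentage points above
the generator's 38.7% truth); at n = 50,000 it is still about +1.7
points. This is the same phenomenon as a model baseline sitting above
raw prevalence in published small-sample Bayesian-network analyses,
and it is why the package reports the model marginal and the raw
prevalence as distinct quantities. Tests that probe *marginal
recovery* therefore use a near-flat prior; tests that probe study
conditions keep `alpha = 1` and document the bias.

## Inference: two engines, hard and soft evidence

All queries are exact. `posterior_by_enumeration()` sums
evidence-weighted joint probabilities over every state (65,536 for the
default schema) and exists as the oracle; `posterior_by_elimination()`
is the production engine — factor-based variable elimination with a
min-degree ordering, declaration-order tie-breaks for bit-stable
output, and agreement with the oracle to 1e-9 enforced across hundreds
of randomized networks in the test suite. Approximate inference is
deliberately absent: at this state-space size exactness is cheap.

Hard evidence fixes a node's state. Soft evidence is implemented as
Pearl *virtual evidence*: a likelihood vector multiplies into the
joint, so the conditioned node ends up observed probabilistically and
the final posterior depends on the interplay with the priors. The
alternative semantics — Jeffrey conditioning, which pins the
conditioned node's marginal exactly — was considered and rejected:
scenario conditioning here is meant to represent an uncertain finding,
not a known population share, and virtual evidence is what makes the
conditioned node's probability "not exactly 1". For scenario queries
built from plain state labels the default likelihood puts 0.9 on the
observed state with the remaining 0.1 spread uniformly; the strength
is a visible, tunable parameter precisely because no canonical value
exists. Degenerate soft evidence (a single nonzero weight) reproduces
hard evidence exactly, and an all-equal vector is vacuous — both are
tested identities. Evidence that is impossible under the network
raises a dedicated error instead of propagating NaN.

## The analysis battery

`baseline_risk()` is the no-evidence marginal of the outcome.
`single_factor_deltas()` conditions on every (predictor, state) pair
in turn and reports signed percentage-point changes from baseline,
sorted by magnitude; within each node the rows satisfy the law of
total probability against the node's marginal, which the tests check
to 1e-9. `run_scenarios()` evaluates compound what-ifs; the four
shipped defaults pair race with region, add advanced age, and spread a
Medicare/Medicaid finding over the two payer states as an explicit
likelihood (in hard mode that spec expands into one run per state,
both reported).

## The synthetic cohort generator

The inpatient database the schema mirrors is licensed and cannot be
redistributed, so the package ships `default_ground_truth()`: a
complete network intended as a *stand-in data-generating process*, not
a reproduction of the real joint distribution. Calibration works as
follows.

* **Root nodes** take published marginal frequencies directly: 58%
  White, 39% aged 40–64, 40% private payer, 37% South, 23% West.
  Frequencies never printed (the remaining race, payer, region and age
  shares, and the income gradient) are set once to realistic US
  inpatient values — e.g. 8% pediatric, income quartiles nearly flat
  with a slight third-quartile excess.
* **Comorbidities** are logistic in age with monotone increasing
  gradients; the intercept is solved by 1-D root finding so the exact
  enumerated marginal hits its target (hypertension 48%, diabetes
  21%). Autoimmune prevalence has no printed target and is set to 12%,
  a realistic inpatient figure.
* **Severity** follows a proportional-odds model shifted by the three
  comorbidities (autoimmune largest, diabetes smallest), giving the
  published "most patients moderate/major" shape.
* **The outcome** is additive on the log-odds scale in its six parents,
  with effect directions matching the reported conditioning gradients
  (older, Black and other-race, lower-income, Medicare/private,
  Midwest/West, higher-severity patients all at elevated risk; the
  second income quartile carries the largest income effect). The
  intercept is again solved so the enumerated high-risk marginal is
  exactly 38.7% — the published value; the companion 38.8% figure that
  appears elsewhere in the source material is a rounding-level
  discrepancy we resolve in favour of 38.7. The constructor verifies
  every calibration target within ±0.5 percentage points and aborts
  otherwise.

`sample_cohort()` draws records by ancestral sampling in topological
order, bit-reproducibly for a given seed, defaulting to n = 441 — the
study scale whose sparsity the smoothing exists to handle.

What the generator does *not* emulate: survey weights, hospital
clustering, interactions (its outcome is additive in log-odds, so a
joint effect like "Black × South" exceeding its parts cannot arise),
missing data (records are complete by construction; "missing" race is
already folded into *Other*), and the real data's unknown higher-order
dependence. Passing tests therefore certify the machinery —
calibration, estimation, inference, validation arithmetic — on a known
truth; they do not certify that real-data conclusions transfer.

## Validation stage

`validate_pipeline()` splits the cohort 70/30 (stratified by outcome
by default — with ~39% positives in a 441-record cohort, unstratified
splits produce unstable panels; the flag turns it off, and the
unstratified split is a plain floor(fraction·n) draw), fits on the
training partition, scores both partitions, and reports the standard
eight-metric panel — accuracy, balanced accuracy, sensitivity,
specificity, PPV, NPV, detection rate, detection prevalence — whose
internal identities (balanced accuracy = (sens+spec)/2, detection rate
= PPV × detection prevalence, accuracy = prev·sens + (1−prev)·spec)
hold exactly on every matrix. Metrics with zero denominators are
reported as `NA`, never coerced. The classification tie at the
threshold goes to *high* — conservative toward detecting at-risk
patients — and the threshold is configurable.

ROC/AUC comes in two deliberate flavours: probability mode (threshold
sweep with tied scores grouped; AUC equals the Mann–Whitney pairwise
statistic, cross-checked in tests against a brute-force oracle and
pROC) and label mode, the two-segment straight-line curve a purely
discrete prediction produces, whose AUC is exactly
(sensitivity+specificity)/2. Both are always computed because a
discrete classifier's published straight-line AUC is only
interpretable in the second form.

## Numerical and design choices

* CPT rows must sum to 1 within 1e-9; enumeration and elimination must
  agree within 1e-9; serialization uses 17 significant digits so
  fitted networks round-trip exactly.
* Parent configurations enumerate column-major over declared category
  orders, making counts, CPT layout and JSON output bit-stable.
* Category labels match case-insensitively after trimming; unknown
  labels are errors with row/column context, never coerced.
* Elimination order is min-degree with declaration-order tie-breaks;
  on graphs this small optimality is irrelevant but determinism is a
  contract.
* All randomized entry points (`sample_cohort()`, `split_cohort()`)
  take explicit seeds and restore the caller's RNG state.

Problem sizes used by the test suite are chosen to make each property
measurable rather than to stress hardware: oracle-equivalence sweeps
use hundreds of randomized networks of up to 10 nodes; convergence
checks sample 1k–50k records; seed sweeps use 20 replicates at
1,500–5,000 records.

## Known limitations

* With six parents, the outcome's 4096-row table is never densely
  observed at realistic cohort sizes: per-row estimates remain
  prior-dominated, the fitted baseline is biased toward 0.5 at study
  scale, and fitted-model discrimination approaches the generator's
  Bayes-optimal AUC only slowly with n. On a reduced structure whose
  outcome parents are age and severity (16 rows), all of these
  recover quickly — an argument for sparser outcome parent sets when
  cohorts are small.
* The additive log-odds truth encodes no interactions, so scenario
  effects that exceed the sum of their parts cannot be generated
  synthetically.
* The severity and mortality-risk inputs derive from a proprietary
  grouper upstream of this package; they are consumed as given
  categories, and any predictor–outcome overlap they embed is
  inherited, not modelled.
* The network is associational. Edge directions follow domain
  narrative, and reversed or cyclic real-world relationships (e.g.
  illness affecting income) are outside the model class.
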