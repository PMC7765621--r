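---
title: "Disproportionality analysis and risk-factor modelling for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis and risk-factor modelling for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(srssignal)
library(dplyr)
```

# The problem

Spontaneous adverse-event reporting systems — here the JADER layout used by
the Japanese PMDA — collect case reports consisting of a demographics record
(DEMO), one row per reported drug with an involvement judgement (DRUG), and
one row per reported MedDRA preferred term (REAC). They have no denominator:
we observe only reports, never the population at risk. The standard
case/non-case answer is *disproportionality*: for a drug D and an event E,
compare how often E appears among reports mentioning D against its frequency
among all other reports. `srssignal` implements this workflow end to end for
the motivating application of medication-related osteonecrosis of the jaw
(MRONJ) and the wider family of osteonecrosis-related side effects, together
with a synthetic report generator that makes every stage testable without the
external database.

# Cleaning model

The ingestion contract mirrors how such databases are actually prepared:

* only **suspected** drugs enter the analysis; concomitant and interaction
  rows are dropped (`filter_suspected()`);
* exact duplicate rows, and within one case repeated drug names or repeated
  preferred terms, collapse to one (`deduplicate()`); the operation is
  idempotent and order-stable, and all downstream counting is at the case
  level (sets, not rows);
* the three tables are merged on the case identifier into one row per DEMO
  case (`merge_cases()`); cases missing from DRUG or REAC keep empty sets;
* reported decade age bands map to their midpoints (`"70s"` → 75); exact
  numeric ages pass through. The source database reports decades, so some
  mapping is unavoidable; the midpoint is the least-informative unbiased
  choice and introduces a uniform ±5-year rounding error whose variance
  (about 8 years²) is small against the population age variance (about
  450 years²), attenuating regression slopes on age by under 2%;
* weights above 60 kg are recoded to 65 kg and below 10 kg to 5 kg
  (`recode_weight()`), reflecting the open-ended bands in which extreme
  weights are reported; the rule is applied to numeric values as well as to
  the literal band labels `">60 kg"` / `"<10 kg"`;
* records with a computable BMI below 5 or at/above 100 are removed as
  data-entry artefacts (`clean_bmi()`; the upper bound is inclusive, the
  lower exclusive). Records whose BMI cannot be computed are **kept**:
  missingness is handled per analysis by complete-case restriction, so the
  cleaning step only removes demonstrable outliers. `cleaning_report()`
  returns the exact conservation accounting
  (`n_input = n_output + n_removed_low + n_removed_high`).

# Disproportionality model

For each drug × event pair the case table is cross-tabulated
(`build_contingency()`):

|            | event      | no event   |
|------------|------------|------------|
| drug       | a          | b          |
| no drug    | c          | d          |

The reporting odds ratio is the cross-product ratio on **half-corrected**
cells (Haldane–Anscombe: 0.5 added to all four cells, unconditionally, not
only when a cell is zero):

$$\mathrm{ROR} = \frac{(a+\tfrac12)(d+\tfrac12)}{(b+\tfrac12)(c+\tfrac12)},
\qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac{1}{a+\frac12}+\tfrac{1}{b+\frac12}+\tfrac{1}{c+\frac12}+\tfrac{1}{d+\frac12}}\Big).$$

The correction guarantees finite, positive estimates for never-co-reported
pairs, at the price of a small shrinkage toward 1 that vanishes as the cells
grow (tested by scaling). Significance uses the **two-sided Fisher exact
test on the raw integer cells** — exact tests are defined on integers, so the
half correction applies only to the odds-ratio scale; this is the only
reading consistent with applying both devices to the same table. The
two-sided p sums hypergeometric probabilities of all tables (margins fixed)
no more probable than the observed one; ties at floating-point precision are
included via the conventional `1e-7` relative tolerance. A pair is flagged as
a signal when `ROR >= 1` and `p < 0.05` (`detect_signals()`). The criterion
deliberately uses the exact p, not the Woolf interval: the two can disagree
near the boundary (e.g. the table a=8, b=8, c=13, d=44 has a Woolf interval
excluding 1 but p = 0.058, and is therefore *not* a signal); the test suite
pins this behaviour. No multiplicity adjustment is applied, matching the
screening convention this package reproduces; the resulting type-I behaviour
is measured empirically on null simulations instead of assumed.

Volcano coordinates are `ln(ROR)` against `-log10(p)` with p floored at
`1e-300` so that underflowing p-values keep finite ordinates
(`volcano_table()`, `autoplot()`).

```{r volcano-demo}
sim <- simulate_reports(synth_config(n_cases = 20000, seed = 1,
                                     baseline_event_logit = -4.5))
cases <- merge_cases(deduplicate(filter_suspected(sim$drug)),
                     deduplicate(sim$reac), sim$demo) |>
  clean_bmi()
detect_signals(cases, event_terms = "osteonecrosis of the jaw")
```

# Demographics comparison

`summarize_groups()` reproduces the patient-background table: complete-case
n / mean / SD per group (SD with the n−1 denominator), the two-sided Wilcoxon
rank-sum test for continuous variables and Fisher's exact test for sex. The
rank-sum test uses mid-ranks, tie-corrected variance and a continuity
correction on the normal path; for combined samples of at most 20 the p-value
comes from exhaustive enumeration of all group assignments of the pooled
mid-ranks, which remains valid under ties. On continuous data the two paths
agree to within 0.01 at the cutover size; under heavy ties the exact path is
the trustworthy one, which is why the enumeration (rather than a no-ties
shortcut) is used. At database scale only the normal path is ever exercised.
The groups being compared are independent (event cases versus all others),
so the rank-sum — not the paired signed-rank — test is the applicable one.

# Logistic risk model

`build_design()` codes one row per complete case: 0/1 suspected-drug
indicators, `female` (male = 0), and age/height/weight in natural units;
`fit_risk_model()` maximises the binomial likelihood by IRLS. Reported per
term: the Wald standard error and p, the **unit odds ratio** `exp(beta)`,
and for continuous terms the **range odds ratio** `exp(beta * (max - min))`
over the observed span, which expresses a per-unit effect as the multiplier
across the whole observed range (a per-year OR of 1.02 over a 90-year span
is a range OR of about 5.9). Model fit is summarised by McFadden's
pseudo-R² `1 - logL/logL0`, the "RSquare (U)" flavour reported by common
commercial software; for a 0/1 outcome it reduces to one minus the deviance
ratio. Separation is surfaced (warning plus `converged = FALSE`, detected
from essentially-degenerate fitted probabilities together with a diverging
coefficient), never silently penalised — fidelity to plain maximum-likelihood
output with explicit diagnostics was preferred over Firth-style shrinkage.

# Event-profile PCA and clustering

`build_ror_matrix()` assembles the drug × event matrix of `ln(ROR)` values
(drugs are observations, events variables; the half correction keeps every
cell finite). Events reported fewer than `min_reports = 20` times are
excluded first — rare columns are dominated by the correction and carry
little signal. `profile_pca()` standardises columns and eigendecomposes the
correlation matrix; *loadings* are variable–component correlations
(eigenvector × √eigenvalue, so the squared loadings of a variable sum to 1),
*contribution ratios* are eigenvalue shares in percent. Eigenvector signs
are mathematically arbitrary, so each component is oriented to make its
largest-|loading| entry positive; this fixed rule makes loadings, scores and
the clustering below reproducible across linear-algebra backends.
`ward_cluster()` then clusters the events on their first three component
loadings with Ward's minimum-variance criterion on Euclidean distances (the
`ward.D2` dialect — the commercial software behind the motivating analysis
does not document its exact dialect, so the standard one was chosen), and
`cut_clusters()` cuts the dendrogram, by default into two groups. On
synthetic data a planted "osteoclast-like" mechanism loading a subset of
events for antiresorptive-type drugs is recovered as its own cluster.

# The synthetic report generator

`synth_config()` / `simulate_reports()` define the study conditions under
which the pipeline is validated. Per case: sex ~ Bernoulli(0.485 female);
age ~ Normal(59, 21.7) truncated to [0, 100] years, emitted as decade bands;
height and weight conditionally normal by sex (females ≈ 153 ± 7 cm,
52 ± 10 kg; males ≈ 165 ± 7 cm, 62 ± 11 kg; height–weight correlation 0.4)
— values near the published background table of the motivating study. Drug
exposures are independent Bernoulli draws by default; an optional Gaussian
copula induces co-prescription correlation to exercise the
univariate-versus-adjusted contrast. Each event is Bernoulli with log-odds
`baseline + Σ drug effects + female effect + age effect × (age − 60) +
height effect × (height − 156)` — continuous covariates enter centred so the
baseline logit is interpretable as the event rate of a reference male.
Field-level missingness (defaults: sex 2%, age 7%, height 35%, weight 30%,
mirroring the heavy height/weight missingness of real extracts), exact
duplicate rows (5%) and optional concomitant-drug rows complete the
emulation. Everything is reproducible from the seed, and the latent
exposure/event indicators are returned as ground truth.

What the generator does *not* emulate: free-text drug-name variants,
Japanese-language fields, sub-case report amendments, non-exact (fuzzy)
duplicates, and reporting-induced dependence between drugs and events beyond
the designed effects. Passing recovery tests therefore demonstrates the
correctness of the estimators under the designed data-generating process,
not robustness to real-world coding noise.

# Validation design and problem sizes

The test suite validates each stage against an independent oracle: Fisher p
against exhaustive `lchoose`-based enumeration (and `stats::fisher.test` as a
library cross-check), the rank-sum exact path against `stats::wilcox.test`,
the single-predictor logistic MLE against the closed-form log cross-product
ratio, PCA against its two-variable closed form (a correlation of r gives a
first-component contribution of 100·(1+r)/2 %) and `prcomp`-style spectral
identities. Statistical recovery uses fixed-seed simulations whose sizes
were chosen so that Monte-Carlo error is small against the tested
tolerances: 200,000 cases for the single planted ROR of 20 (5% exposure, 1%
baseline event rate), 1,000 replicates of 5,000 cases for Woolf-interval
coverage at OR = 5 (10% exposure, baseline logit −2.5, giving expected cells
of roughly a ≈ 115 so the log-normal asymptotics apply), and 100,000 cases
for the multivariate logistic recovery (effects ln 20 for the drug, ln 1.3
for female, ln 1.02 per year, ln 0.99 per cm — the structure of the
motivating risk model), each parameter required to land within 3 standard
errors of its design value.

# Known limitations

* Real PMDA distributions are Shift-JIS CSV with Japanese headers; the
  reader takes an explicit encoding and column map, but no Japanese value
  translation is attempted.
* Record linkage is exact-key only; the upstream deduplication literature
  describes richer heuristics that are out of scope and replaceable behind
  `deduplicate()`.
* Only ROR-based disproportionality is provided — no PRR, Bayesian shrinkage
  (BCPNN/EBGM) or multiplicity control.
* The logistic model is plain ML: no interactions, variable selection or
  penalisation; with very sparse drug indicators quasi-separation is
  reported rather than repaired.
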