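---
title: "Automated PESI scoring from EHR snapshots, and how we validate it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated PESI scoring from EHR snapshots, and how we validate it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(autopesi)
```

## The problem

The Pulmonary Embolism Severity Index (PESI) stratifies acute pulmonary
embolism patients by 30-day all-cause mortality. Patients in classes I-II
(score below 86) are "low risk" and are candidates for outpatient
management, yet the score is rarely computed at the bedside: it has 11
weighted inputs, several of them ambiguous ("history of cancer"?), and it
drifts as vitals are recharted during the ED stay. An EHR-embedded
calculator can compute the score automatically at the instant a CT
pulmonary angiogram (CT-PE) is ordered — but then it scores *what is
documented at that instant*, not what is clinically true. The gap between
the two is exactly what a validation study against blinded physician chart
review measures.

`autopesi` implements all three layers of that problem:

1. **the calculator** (`compute_pesi()`): derives the 11 PESI variables
   from a structured encounter snapshot as of a trigger timestamp;
2. **the documentation process** (`generate_cohort()`): a synthetic paired
   cohort generator whose error model reproduces the failure modes that
   separate an automated score from a physician's;
3. **the validation statistics** (`evaluate_agreement()` and friends):
   exact binomial confidence intervals, Cohen's kappa, logistic odds
   ratios, Bland-Altman limits of agreement, per-component error tables.

## The score

The PESI total is `age_years` plus fixed points for each adverse binary
component:

| component | criterion | points |
|---|---|---|
| male sex | sex assigned at birth | +10 |
| history of cancer | hierarchical SNOMED match | +30 |
| history of heart failure | hierarchical SNOMED match | +10 |
| history of chronic lung disease | hierarchical SNOMED match | +10 |
| tachycardia | peak HR >= 110 /min | +20 |
| hypotension | lowest SBP < 100 mmHg | +30 |
| tachypnea | peak RR >= 30 /min | +20 |
| hypothermia | lowest temperature < 36 °C | +20 |
| altered mental status | GCS < 14 or AMS chief concern | +60 |
| hypoxemia | SpO2 < 90 %, O2 > 2 L/min (absolute or above home
  requirement), or assist device | +20 |

Classes: I < 66, II 66-85, III 86-105, IV 106-125, V > 125; low risk is a
total below 86. The weights and boundaries are carried as data
(`pesi_weights()`, `class_boundaries()`) so alternative weightings are
configurable without touching the engine.

Two textual sources for the class-II upper bound disagree (66-86
inclusive vs low risk strictly below 86); we resolve in favor of the
strict cut — class II ends at 85 — which is the only choice consistent
with a 203/297 low/high split and with the standard published index.

### Derivation rules worth spelling out

**Peak vitals.** "Peak" means the extremum in the *adverse* direction for
each criterion: maximum HR and RR, minimum SBP, temperature and SpO2. Only
samples timestamped at or before the trigger are visible; this is a causal
boundary, not a filter — data charted later must not change the score, and
a property test asserts exactly that. Missing vital kinds contribute no
points and report provenance `"absent"`, because the production setting
scores whatever is charted, never errors out.

**Comorbidities.** An entry on the active problem list or past medical
history counts for a category if its SNOMED concept equals or is an is-a
descendant of a category root and is not excluded. `resolved` entries are
ignored unless explicitly opted in: the data sources named for the score
are the *active* problem list and the past medical *history*. The package
ships a small hand-built illustrative graph (file names carry a
`synthetic_` prefix); institutional value sets are site-specific, so real
deployments load their own with `load_concept_graph()`. Exclusion sets
default to empty — matching plain hierarchical behavior — but exist
because questions like "does non-metastatic skin cancer count?" are
configuration points, not code.

**Hypoxemia.** The four clauses (SpO2 < 90; flow > 2 L/min; flow > home
requirement + 2; assist device) are evaluated as a literal disjunction. As
written, a patient on a chronic 4 L/min home regimen triggers the absolute
clause even at baseline. We implement the literal rule and provide
`suppress_absolute_flow_when_home_o2` (default off) for sites that prefer
the relative-only reading for home-oxygen patients.

**Altered mental status.** GCS below 14 before the trigger, or the AMS
chief concern — matched either as the coded concept (419284004) or as
case-insensitive text, since whether the production tool matched a code or
free text is not determinable; supporting both is the tolerant choice.

**Sex.** Points use sex assigned at birth when known; otherwise the
administrative sex is used with a warning. The distinction matters: the
one documented sex error in the motivating study arose from conflation of
the two fields, and the simulator reproduces that mechanism.

## The synthetic cohort and its error model

`cohort_config()` defaults *are* the validation study's conditions: 500
patients, age 58.2 (SD 17.7, truncated at 18), 43.8% male, prevalences of
37% / 17.6% / 41% for cancer / heart failure / chronic lung disease, 10%
first-visit patients, 8% with acute PE on CT. Vitals are drawn per kind
from truncated normals (HR 88/18, RR 19/5, SBP 128/22, TEMP 36.8/0.5, SPO2
96.5/2.5, three samples per kind before the trigger); rates not printed
anywhere (altered mental status 4%, supplemental oxygen 12%, assist device
3%, home oxygen 5%) were chosen once as ordinary ED plausibility and are
not tuned. No physiologic coupling between vital kinds is modeled: the
engine consumes only extremes, so marginal distributions are the
load-bearing part.

Each patient yields a pair: `truth` (complete, timely — what a blinded
abstractor reconstructs) and `documented` (what the calculator sees).
The error model applies three mechanisms:

* **Comorbidity omission** — with the configured probability, a true
  carrier's category codes are simply absent from the documented problem
  list and history. The probability is *conditional on carrying the
  comorbidity*: omission 1 means no documented carrier anywhere. Defaults
  (0.227 / 0.182 / 0.132) are the study's marginal component error rates
  divided by its prevalences, so the simulated cohort reproduces the
  observed marginal error rates (8.4% / 3.2% / 5.4%). First-visit patients
  get 3 times the omission rate of established patients; the two arms are
  normalized so their mixture equals the configured rate, with the
  first-visit arm saturating first so that a rate of 1 stays a certainty.
* **Vitals latency** — with per-patient probability (default 4.6%), a
  transient threshold-crossing vital is measured shortly before the
  trigger but charted half an hour after it: the abstractor sees it, the
  calculator cannot. The injected kind is the first of HR, RR, SBP, TEMP,
  SpO2 whose criterion the patient does not already meet, which makes
  every applied error detectable and the configured probability a
  recoverable per-patient rate.
* **Sex conflation** — with probability 0.2%, the documented sex assigned
  at birth is replaced by a differing marker.

What the generator deliberately does not emulate: spurious (stale)
problem-list entries — errors here only ever under-score the documented
record, whereas real problem lists can also over-score; correlated errors
across components within a patient; non-stationary error rates over the
study window; and anything about PE pathophysiology or CT results (the
acute-PE flag is an independent covariate, as the validation design
intends). Passing tests on this cohort therefore demonstrate that the
pipeline estimates what was injected, not that real EHR error processes
are this simple.

`score_pair()` computes the gold standard from `truth`, the automated
score from `documented`, and tags an error component when its point
contribution differs between the two — equivalent to asking whether
substituting the component's true value moves the documented total toward
the truth. Vital and oxygenation criteria pool into a single `vitals` tag,
sex and mental status into `other`, mirroring how component errors are
reported in this literature.

## The study replica

Acceptance-style checks must not depend on RNG, so the published results
table is reproduced by *construction*, not simulation:
`build_study_replica()` deterministically emits 500 records hitting every
printed marginal simultaneously — 394 exact matches, 442 class and 477
risk-band agreements, the 15/8 discordance split, class counts
112/91/84/80/133, 203 low-risk, 50 first-visit, 40 acute-PE, and component
error tags 42/16/27/23/1. Where the joint distribution is unprinted the
construction is minimal: 109 tags across 106 mismatched patients means
exactly three patients carry a double error (cancer + vitals), and each
mismatch is the smallest perturbation its component weights allow (a
cancer tag shifts a score by 30, heart failure by 10, and so on). A
consistency check recomputes every marginal at build time and fails loudly
rather than drift.

```{r}
records <- build_study_replica()
report <- evaluate_agreement(records)
report
```

## Statistical choices

* **Exact binomial CI** (`exact_binomial_ci()`): Clopper-Pearson from beta
  quantiles, matching the "binomial test" reporting convention. The
  replica's 394/500 reproduces the published 74.9%-82.3% interval within
  0.2 percentage points; the residual is rounding/method ambiguity in the
  original report, which does not name its interval flavor. Tests pin the
  implementation to an independent bisection of the binomial CDF at 1e-8.
* **Cohen's kappa** (`cohen_kappa()`): computed from the contingency-table
  definition with the standard large-sample standard error
  `sqrt(p_o(1-p_o)/(n(1-p_e)^2))`, clamped to [-1, 1]. A single shared
  label makes kappa undefined and is reported as such, not as 1.
* **Odds ratios** (`logistic_or()`): univariable binomial GLM (IRLS,
  tolerance 1e-10, 50 iterations max). Separation — any empty 2x2 cell or
  a divergent slope — is reported as non-estimable with the offending
  table in the diagnostic. Predictors (gold-standard low risk,
  first-visit) are fitted in separate univariable models; a joint model is
  possible but is not the default because the published table reports them
  singly without stating adjustment.
* **Homogeneity of component error rates**: the primary test is
  chi-square over the per-patient binary error indicators by component;
  a one-way ANOVA over the same stacked indicators is available
  (`homogeneity = "anova"`) for fidelity to how such tables are sometimes
  described, though ANOVA on binary indicators is the less standard
  choice. Both agree that the replica's error rates are heterogeneous
  (p < 0.001).
* **Bland-Altman** (`bland_altman()`): mean difference, SD of differences
  and 1.96-SD limits of agreement, with the per-point series exported for
  plotting rather than a rendered figure.

## Numerical and degenerate-input conventions

Timestamps are ISO-8601 UTC throughout; temperature is Celsius internally,
with Fahrenheit converted at the file boundary so the engine stays
unit-pure. Duplicate or contradictory flowsheet rows at one timestamp are
all preserved — the extremum logic makes the adverse one win, which is the
only defensible tie-break for a severity score. Unknown enum values in
source data degrade to `other`/`unknown` with a warning instead of
failing, because an EHR-embedded tool cannot refuse an encounter over one
dirty row; out-of-range *values* (GCS of 2, SpO2 of 101) are hard
validation errors naming the field, never silently clamped. Scores below
zero are impossible by construction and rejected by `classify_pesi()`.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at the sizes a desk validation
needs: the 500-record replica for the published marginals, 1,000 simulated
patients for the null-error identity (perfect agreement, kappa 1, empty
error table), and 20,000 for parameter recovery, where the injected
omission and latency rates are recovered within three binomial standard
errors. Property checks (closure vs breadth-first reachability, score
monotonicity, trigger causality, classification vs its defining table on
0-300) run on randomized structures under fixed seeds.

## Known limitations

The illustrative concept graph is a toy; results on it say nothing about
any institution's value sets. The simulator's omission-only comorbidity
errors under-represent over-scoring failure modes. Odds-ratio magnitudes
from the replica are not the published ones — reproducing those requires
the patient-level covariate joints, which were never printed; only their
directions (agreement more likely for low-risk scores, less likely for
first visits) are built into the replica. And the package computes a score
at a documented instant: it does not predict mortality, render best
practice alerts, or talk to an EHR.
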