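---
title: "From laboratory results to phenotype associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From laboratory results to phenotype associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phelab)
```

## The problem

Electronic health records carry enormous numbers of laboratory test results,
identified by LOINC codes, but a LOINC code names a *test*, not an *outcome*:
"Potassium [Moles/volume] in Serum" says nothing about whether the patient's
potassium was high, low, or normal. Different tests with different codes can
also share one clinical interpretation (three different glucose assays all
signal hyperglycemia when elevated). `phelab` turns LOINC-coded results
carried as FHIR Observation resources into Human Phenotype Ontology (HPO)
terms through a curated annotation map, aggregates the calls into per-patient
deep phenotype profiles using the ontology's hierarchy, and screens each
phenotype for association with binary clinical exposures.

## The conversion model

The central artifact is the **annotation map**: a keyed table
`(LOINC, outcome) -> (HPO term, negated?)`. Outcomes come in two flavours:

* **internal codes** for quantitative (Qn) and ordinal (Ord) tests:
  `L`, `N`, `H`, `A` (abnormal, direction unspecified), `POS`, `NEG`;
* **external codes** for nominal (Nom) tests, e.g. SNOMED-CT codes for urine
  colors, each mapped to its own term.

HPO contains only abnormality terms, so a *normal* result maps to a *negated*
term (NOT Hyperkalemia's parent, say). The map's invariants enforce this:
`negated = TRUE` is legal only for `N`/`NEG` outcomes, keys are unique, one
scale per LOINC, and the internal code `U` (unknown) is never a key.

Each observation's outcome is resolved with a fixed precedence:

1. an **interpretation code**, if present, normalized to a primary code via
   the published vocabulary table (`normalize_interpretation()` is total and
   idempotent; unknown tokens become `U`, and an explicit `U` fails the
   record as `UNKNOWN_INTERPRETATION` even when a value is present — a lab
   that says it could not interpret a result should not be overridden);
2. for nominal tests (and ordinal tests with a coded value), the **coded
   value** keyed by its coding system;
3. for quantitative tests, **comparison against the reference range**:
   below the low bound is `L`, above the high bound `H`, otherwise `N`.

Numerical choices worth stating: range bounds are inclusive of normal
(a value equal to a bound is `N`, matching the FHIR reading of the range as
the normal interval); no unit conversion is ever attempted — value and bound
units must be string-equal after trimming, otherwise the record fails as
`INSUFFICIENT_DATA`, because silent unit coercion in clinical data is a
safety hazard; when several reference ranges are attached, the first one
without an age/population qualifier is used, else the first. When an
interpretation code and the range disagree, the code wins and the row is
flagged (`range_conflict`) with a warning — the code is the laboratory's own
summary of the result. A resolved `L`/`H` with no specific annotation falls
back to the LOINC's `A` entry when one exists; `N` never falls back, since
"abnormal" cannot describe a normal result.

## Profiles, propagation, and presence

Calls are grouped per patient and term, counting observations and recording
first/last observation times (timestamps are compared lexicographically as
ISO strings; only ordering is needed). Non-negated counts are then
**propagated** up the is_a hierarchy: a patient with Hypokalemia also has
Abnormal blood potassium concentration. Each source observation contributes
at most once to each ancestor (union semantics — a diamond in the DAG does
not double-count), negated calls never propagate in either direction, and
propagation stops below the uninformative roots (`HP:0000118` "Phenotypic
abnormality" and `HP:0000001`), which would otherwise be assigned to every
patient. Propagation is idempotent because only asserted counts feed the
closure.

Presence is three-state. An isolated abnormal measurement may be an
artifact, so a phenotype is **PRESENT** only with at least
`min_obs_for_present = 3` observations over the whole period; a patient is
**ABSENT** for a term only if the term was *never* assigned; anything in
between is **INDETERMINATE**. The threshold is applied to *propagated*
counts by default (`propagate_before_threshold = TRUE`): this is what lets
three observations spread over sibling vitamin-metabolism children make the
parent term PRESENT, which is precisely the aggregation benefit the
hierarchy buys. The switch is exposed for sensitivity analysis because the
opposite order (threshold first, then propagate) is also defensible.

Cohort bookkeeping: patients with medical encounters on fewer than 10
distinct calendar days (counted across encounter, medication, and diagnosis
records) are excluded — rare visitors receive few tests and would look
artificially healthy. Exposures are binary: `frequent_prednisone` is
strictly more than 3 prescriptions; `acute_asthma` is any diagnosis code
matching a configured ICD prefix set (default `J45`/`493`) after stripping
dots from both sides, since extracts disagree on dot conventions.

## The association screen

For each term, the design is: outcome 1 for PRESENT patients, 0 for ABSENT,
INDETERMINATE dropped per term (whether they should be dropped per term or
globally is an open choice; per-term dropping keeps the maximum usable
sample for every term). Terms are excluded when the majority class among
PRESENT/ABSENT reaches `uniformity_threshold = 0.95` (a 96/100 split is
excluded, 94/100 analyzed), or when fewer than `min_patients_per_term`
patients carry the phenotype. The default of 100 carriers is a deliberate,
configurable choice: a minimum-carrier rule is required for the aggregation
story to make sense, and 100 is consistent with subtype counts of at most a
few dozen failing while an aggregate of ~111 passes.

The fit is a maximum-likelihood logistic regression with intercept on both
exposures jointly (`stats::glm`, binomial family, convergence tolerance
1e-10), standard errors from the observed information, two-sided Wald
p-values. Odds ratios are `exp(beta)` with confidence intervals
`exp(beta ± 1.98·SE)` — the multiplier is 1.98 exactly, kept as printed in
the methodology this package operationalizes, and configurable via `ci_z`.
Significance markers are `**` for p < 0.01, `*` for p < 0.05, `-`
otherwise; a Benjamini–Hochberg column is emitted alongside for
transparency but deliberately does not drive the markers, mirroring the
single-test reporting convention of the original analysis. Separation and
non-convergence (|beta| or SE above 15, or glm failing to converge) yield a
typed `NON_CONVERGED` status rather than an error, so one pathological term
cannot kill a screen.

## The synthetic cohort generator

No real EHR extract can ship with a package, so the generator *is* the
study system, with known ground truth:

* exposures: asthma diagnosis with prevalence 1/3; frequent prednisone use
  with probability 0.142 given asthma and 0.085 otherwise (≈ 10.4%
  marginal), matching the kind of respiratory cohort the method targets;
* encounter histories: distinct encounter days ~ Poisson(24) (floored at
  10), with a 5% low-visit fraction (3–9 days) to exercise the exclusion;
* per-term presence drawn from `logit(p) = logit(baseline) + β₁·prednisone
  + β₂·asthma` with planted β's; the default panel plants strong prednisone
  effects (OR 3.74, 2.48, 2) on blood phenotypes, modest asthma effects
  (1.17–1.7) on eosinophilia and two vitamin-metabolism children, and one
  null term;
* observations: a PRESENT patient receives 3 + Poisson(1) abnormal results
  of the term's synthetic panel LOINC (reserved 9xxxx code space), an
  absent patient 1 + Poisson(1) normal results. Abnormal values are drawn
  uniformly from the half-range band beyond the violated bound and normal
  values uniformly within the range — crude, but only the L/N/H partition
  matters downstream, so distributional realism is explicitly out of
  scope;
* 30% of observations carry only an interpretation code (no value),
  exercising the code path of the algorithm; a configurable fraction of
  observations carry unannotated LOINC codes (each mapped observation
  spawns an unmapped companion with probability u/(1−u), so the expected
  unmapped share is u);
* everything is seeded: the same spec reproduces the cohort byte for byte.

What passing tests on this generator do **not** show: robustness to real
EHR messiness — unit heterogeneity, free-text values, multi-component
panels, missing-not-at-random testing, temporal confounding. The generator
emulates structure, not epidemiology.

## Verification strategy and problem sizes

The suite checks each layer against an independent oracle: annotation
lookups against a linear scan; ancestor closures against boolean-matrix
reachability on 100 random DAGs of up to 30 nodes; collection conversion
against per-record reconversion; the logistic fit against the closed-form
2×2 cross-product ratio (agreement to 1e-6); CI identities recomputed from
beta/SE on every emitted row. Statistical calibration uses the direct
harness (`simulate_association_cohort()`), which skips FHIR emission:
planted log-ORs of {0, log 1.5, log 3} recovered with absolute bias below
0.1 — measured as the mean estimate over 8 replicate cohorts of n = 5000,
since a single draw at that size has a sampling SE of the same order as the
bias bound — plus CI coverage of a planted OR 3 over 20 seeds at n = 2000,
and a null false-positive band over 200 replicate null terms at n = 1000.
These sizes keep the default suite comfortably under a minute of
statistical testing while leaving the binomial tolerances meaningful.

## Known limitations

* Free-text (`valueString`) results are never interpreted; NLP is out of
  scope.
* Multi-component (panel) Observations are skipped with a distinct reason
  rather than decomposed.
* No covariate adjustment (age, sex) and no longitudinal modelling; the
  screen is a cross-sectional proof-of-principle by design.
* LOINC check-digit validation is format-only by default so synthetic code
  spaces remain usable.
* The OBO reader covers the OBO 1.2 subset the fixtures and the public HPO
  release use (`id`, `name`, `is_a`, `alt_id`, `is_obsolete`,
  `replaced_by`); exotic tags are ignored.
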