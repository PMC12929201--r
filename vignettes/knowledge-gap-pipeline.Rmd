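---
title: "Methods: knowledge-gap landscapes and pharmacovigilance screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-gap landscapes and pharmacovigilance screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pharmgap)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data validation does
and does not demonstrate.

## The label model

Every abstract is either non-relevant or carries a nonempty subset of the
study-type labels {PK, PE, CT} subject to one structural constraint: **PE
and CT are mutually exclusive** (an article reporting a clinical trial is
not also counted as an observational pharmaco-epidemiology study), while PK
may co-occur with either. The five admissible relevant combinations are
therefore PE, CT, PK, PK+PE, PK+CT. `annotated_corpus_counts()` ships the
published manual-annotation counts of these combinations (1363, 512, 269,
588, 46, plus 2067 non-relevant abstracts of 4845 total); the corpus
generator's default `label_mix` and `relevant_fraction` are taken from
exactly these proportions, so synthetic corpora reproduce the label
structure of the real one. The constraint is enforced wherever labels enter
the system (`annotate_corpus()` raises an invariant error on a PE+CT set).

## Lexicon hygiene and scanning

Text scanning is deliberately simple — case-insensitive word-boundary
matching — and all the subtlety sits in vocabulary hygiene, where false
positives actually originate:

* synonyms are case-folded and whitespace-normalized;
* dosage-like tokens (a number attached to mg/ml/mcg/g/%) are removed;
* synonyms **shorter than five characters are excluded** ("ASA" inside
  ordinary prose is not evidence of aspirin);
* a synonym appearing under two canonical names is ambiguous and is dropped
  from *all* entries rather than assigned by priority — with no stated
  assignment rule, dropping is the only choice that cannot silently
  misattribute a paper.

Drugs are scanned over title, abstract, keywords, and MeSH terms;
populations over title, abstract, and MeSH terms only. The asymmetry is
intentional: the population vocabulary is described for those three fields
only, and we follow that letter rather than guess (the one place the
upstream description is ambiguous, flagged here rather than resolved
silently). Diseases are taken from MeSH headings restricted to the C
(disease) and F (psychiatry/psychology) trees.

Publication counts are **distinct-record counts**: a drug mentioned five
times in one abstract counts once, and a record with d drugs, p
populations, and s study types contributes one unit to each of the d×p×s
cells.

Claims drug names pass through `clean_claims_drug_name()`: multi-ingredient
products are split on "-", "/", ";", " with ", " and " (the delimiter set
is our choice; the upstream description only states that decomposition
happens), category names (vaccines, allergenic extracts, prenatal vitamins,
lotions, kits) are removed outright, and source/process/salt tokens are
stripped.

## Triage evaluation

The classifier is an injected interface (`fit`/`predict` on text chunks);
the reference implementation is a ridge-penalized logistic regression on
sparse token counts (`glmnet`), evaluated at a single fixed penalty.
Records are assembled title ⊕ abstract ⊕ MeSH ⊕ keywords, whitespace
tokenized, and cut into non-overlapping chunks of `max_chunk_len` tokens
(default 512, the conventional transformer budget). Chunk scores are
**max-pooled** per record: any positive chunk flags the record. Pooling is
unspecified upstream; max-pooling is chosen because a study-type cue
anywhere in an abstract is sufficient evidence for the label.

Cross-validation is stratified (both classes in every fold) with a fixed
seed, each record predicted exactly once as a held-out item, and the
binary task is *study-type-positive versus non-relevant*. Because it is
unstated whether reported metrics were pooled across folds or averaged per
fold, `crossval_evaluate()` returns both (`$pooled`, `$fold_metrics`).

Calibration (`calibration_pass()`) re-reviews exactly the misclassified
ids. With a truthful reviewer every change converts a false positive to a
true positive or a false negative to a true negative, so pooled F1 can
never decrease — the property the acceptance suite asserts; the magnitude
of the improvement depends on the noise rate and is not asserted.

Inter-annotator agreement is **exact-tuple** agreement (relevance plus the
full study-type set). The published 72.16% rate is not decomposed per
label, so the stricter definition is used and documented.

## Claims windows and the landscape

A pregnancy episode is anchored at the person's **first** delivery-coded
event. Eligibility requires merged enrollment spans to cover
[index−270, index+180] with no gap (spans touching on adjacent days count
as continuous). The prescription windows partition the episode:

* pregnancy: [index−270, index−1]
* postpartum: [index, index+180]

The index day itself is postpartum — the upstream text assigns "from the
index date" to the postpartum period, which forces the pregnancy window to
end at index−1; this half-open convention is applied everywhere (exposure
windows below are the one exception, deliberately, since a fill on the
index day is still a pregnancy fill).

Pediatric ages are assigned per calendar year from age at the year start,
with half-open groups [0,1), [1,12), [12,18]; "0–1, 1–12, 12–18" is
ambiguous at the shared endpoints, and the half-open reading means a child
aged exactly 1 is in the 1–12 group. Sample sizes are cumulative
person-years across the five-year window; person-years before birth are
skipped (count kept in the `n_negative_age` attribute). Prescription
counting is event-level (every fill counts) with a `distinct_persons` flag
for person-level counting; rates are also reported per 1000 persons.

"More than 10 prescriptions" is read strictly (> 10). Evidence classes cut
at 0 (none), 1–4 (weak, i.e. fewer than five papers), ≥ 5 (adequate), and
the gap measure is (no + weak)/total over each subpopulation's
prescribed-drug universe, with unpublished drugs counting as 0 papers.
Publication population tags map onto claims subpopulations through
`default_population_map()` (e.g. neonate/newborn/infant/preterm → ages
0–1); the mapping is a package convention, applied identically to the
pipeline output and to the ground-truth derivation it is compared with.

## Disproportionality statistics

PRR and ROR use the standard log-scale Wald lower bounds. Zero cells make
the bounds undefined; a continuity-correction flag (+0.5 to all cells) is
available but **off by default**, since the upstream description is silent
and an uncorrected default keeps estimates exactly at their textbook
values. Undefined statistics make a pair a non-signal with a reason code,
never an error.

For the information component we use the gamma–Poisson shrinkage
formulation: IC = log2[(n11+0.5)/(E+0.5)] and IC025 the *exact* 2.5th
gamma quantile of the posterior λ ~ Gamma(n11+0.5, E+0.5). The original
1998 normal-approximation variant is intentionally out of scope: the
shrinkage form is modern practice, has no approximation error to audit,
and its bound is Monte-Carlo-validated in the test suite to 0.01 against
10⁶-draw posteriors.

The MGPS prior — mixture p·Gamma(α₁,β₁) + (1−p)·Gamma(α₂,β₂) on the
relative reporting rate λ, with n11 ~ Poisson(λE) marginally a
negative-binomial mixture — is fitted once per database over all pairs
(database-wide fitting is standard MGPS practice; per-drug subsets would
starve the prior). Optimization is bounded quasi-Newton (L-BFGS-B) on
log/logit-transformed parameters from the canonical start (0.2, 0.1, 2.0,
4.0, 1/3), augmented with a unit start and a moment-informed start because
the marginal likelihood has ridges along which a single start can stall on
a parameter bound; the best converged optimum wins, and non-convergence of
all starts raises an error carrying the best-so-far parameters. EBGM is
computed from exact digamma expressions for E[log₂ λ]; EB05 by
root-finding on the two-component posterior mixture CDF to 10⁻⁸.

Signal thresholds are strict inequalities (IC025 > 0, PRR025 > 1,
ROR025 > 1, EB05 > 1): a bound exactly at its threshold is a non-signal.
Stratification is not implemented; the intended use restricts the report
database to a single age stratum (e.g. ages 0–2) by filtering.

## The nested case-control screen

"Two months" is implemented as 60 days. Exposure is any fill of the drug
inside the pregnancy period [index−270, index]; the window anchors at the
**first** qualifying fill and is clamped at the index day when it would
overrun. The largest inference in the whole package is the control
comparison window: nothing upstream says how unexposed persons'
observation windows were anchored, so we sample control window offsets
(seeded) from the empirical distribution of exposed offsets — controls
then observe the same distribution of pregnancy time as cases, which is
the property the chi-square contrast needs. Outcomes are person-level
indicators (a code counts once no matter how many in-window diagnoses).

The test is Pearson's chi-square without continuity correction at the
fixed threshold p < 10⁻⁵; that single stringent level is the
multiple-testing control, and no FDR procedure is layered on top. No
covariate matching is performed. Blocklist filtering is prefix-based with
fixed precedence (pregnancy-related, indication-related, label-known,
literature-known); filtered codes are retained in the output with their
reason and excluded only from the new-ADE report.

## The synthetic-data generators

The generators define the validation conditions; they are not tuned to any
particular test outcome.

**Corpus.** Per-drug paper counts follow a Zipf law over the drug list
(exponent 1 by default — the canonical heavy-tailed choice for
publication-frequency data); the relevant fraction and label mix default to
the published annotation counts; each assigned drug name is embedded
verbatim in exactly one of title/abstract/MeSH chosen uniformly, exercising
every scan field; each study type leaves a distinct token footprint so the
corpus is classifier-separable; filler vocabulary is disjoint from every
lexicon so annotation can be validated for exact truth recovery.

**Reports.** Drugs and events enter reports independently with configured
margins (defaults 0.02–0.08 across the vocabulary, giving realistic
multi-drug, multi-event reports); an injected pair's joint probability is
set to λ·p·q with both margins preserved, so its relative reporting ratio
is λ by construction (feasibility requires λ ≤ 1/max(p, q), validated).
Empty reports get a fill-in drug/event from the *non-injected* vocabulary,
which keeps every report nonempty without touching injected margins.

**Claims.** Dates are integer day numbers over a five-year window
(365-day years, days 0–1824); windows are day counts, so no calendar
arithmetic exists anywhere. Pregnant persons carry one delivery event; a
configurable fraction receives enrollment spans violating the 270/180
continuity requirement so the filter is exercised. Null ICD-10 codes are
scattered over the pregnancy period at a per-day rate calibrated so any
60-day window contains one with the configured probability; injected ADE
codes appear inside exposed persons' exposure windows at `exposed_rate`
and elsewhere at the calibrated baseline — making the exposed/unexposed
rate ratio recoverable by the screen.

The marginal distributions of real spontaneous-report and claims data are
not described by any source available to this package; the defaults above
are stated conventions chosen once for realism. Consequently, passing
tests demonstrate that the *methods* recover what the generators plant
under plausible statistical structure — heavy-tailed publication counts,
sparse drug×event co-occurrence, windowed event elevation — not that they
reproduce proprietary-data percentages, report deduplication, MedDRA
hierarchies, or claims-dialect quirks, all of which are out of scope.

## Validation sizes

The acceptance suite runs at the sizes the validation design states: a
200-table random grid for oracle equivalence (10⁶ Monte-Carlo draws per
table for IC/EBGM), 5000 pairs × 10 seeds for MGPS parameter recovery
(mean estimates within 25%), 50,000 reports × 20 seeds for injected-signal
recovery (sensitivity ≥ 0.9, false-flag rate ≤ 5%), 3000 pregnant persons
× 100 null codes × 20 seeds for type-I control (zero flags in ≥ 18 seeds)
plus one 20,000-person power run, a 1500-paper/4000-person end-to-end
landscape equality check, and a 2000-paper, 5%-noise calibration run.
Unit tests use smaller sizes of the same designs.

## Known limitations

* The reference classifier is a linear token-count model; it validates the
  evaluation harness, not state-of-the-art NLP performance.
* Control-window anchoring in the case-control screen is an inference (see
  above) and the screen performs no confounder adjustment.
* The generators produce structurally faithful but distributionally
  conventional data; absolute gap percentages from synthetic cohorts carry
  no real-world meaning.
* MeSH tree handling is prefix-based over supplied term→code maps; no
  MeSH release files are parsed.
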