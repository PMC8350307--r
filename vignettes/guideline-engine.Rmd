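---
title: "A declarative guideline engine for rhinosinusitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A declarative guideline engine for rhinosinusitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eposcds)
```

## The clinical problem and the model

Acute rhinosinusitis is usually viral and self-limiting; a bacterial
superinfection — the one situation in which antibiotics help — occurs in a
minority of cases, yet antibiotics are prescribed in most of them. The EPOS
guideline gives a crisp, fully symbolic criterion for when bacterial
disease should be considered, which makes the decision ideal for a
knowledge-based system: a small set of if–then rules, no probabilities, no
learned components.

`eposcds` separates the three classic parts of such a system:

1. **Knowledge base** — `inst/extdata/epos2012_rules.json`, eight
   declarative rules over a fixed fact vocabulary.
2. **Inference engine** — `fire_rules()`, a generic monotone forward
   chainer: it repeatedly fires any rule whose antecedent facts all hold
   and whose consequent is new, until nothing changes. Because no rule
   retracts a fact, the fact set grows to a unique fixpoint, independent of
   rule ordering; the test suite checks this by scrambling rule priorities.
3. **Communication** — typed patient records (`symptom_profile`), a CSV/JSON
   schema, and the `cmd_*` command-line surface.

The rule language is purely conjunctive. Negation is handled at the seed
level: `profile_facts()` asserts each primitive predicate *or* its
complement (`signs_ge_3` / `signs_lt_3`, `polyps_absent` /
`polyps_present_or_unknown`, ...). The price is that "chronic disease not
meeting all three macrolide conditions" needs three rules (one per negated
conjunct); the benefit is that the chainer stays trivially monotone and the
knowledge base stays data, revisable to a newer guideline without code
changes.

## Diagnostic parameters and their boundaries

All thresholds come from the guideline text; the package's only freedom was
how to close the boundaries, and every closure is the strict literal
reading:

- **Course**: acute is *less than* 12 weeks, so day 83 is acute and day 84
  is chronic. The boundary day belongs to the chronic side because the
  guideline phrases acute as a strict upper bound.
- **Temporal criterion**: *more than* 10 days (day 10 itself does not
  qualify) or worsening after day 5. Worsening is only accepted on
  profiles of at least 6 days — it is impossible earlier, and the
  validator rejects such records.
- **Fever**: *more than* 38 °C; 38.0 °C exactly contributes no sign.
  Plausibility bounds `[34, 43]` °C catch unit errors.
- **Cardinal-sign threshold**: at least 3 of 5. Tri-state inputs
  (ESR/CRP, polyps, IgE) must be affirmatively `yes`/`no` to drive a rule;
  `unknown` always falls on the conservative side, so missing laboratory
  data can never create an antibiotic indication.
- **Unilateral predominance** of discharge or pain is recorded (and
  validated to require its parent sign) but does not count as an extra
  sign: the guideline lists it parenthetically as a qualifier.

Precedence, where two rule groups could both apply, is fixed as: bacterial
before post-viral in the acute arm (the stronger criterion is tested
first), and postoperative purulent complication before macrolide
eligibility in the chronic arm (the complication is an antibiotic
indication in its own right). The acceptance suite pins the whole decision
function against an independently written flat conditional over an
exhaustive grid of boundary durations, sign combinations and chronic
modifiers.

## What the synthetic cohort emulates — and what it does not

No patient-level dataset is published for the original retrospective
cohort, so the generator emulates its only published structure: the
category counts. The `study_replica` preset holds 335 common-cold, 186
post-viral and 101 bacterial acute patients (622), plus 830 plain chronic
patients and 13 antibiotic-indicated chronic ones (843; 1465 in all). The
published tables give only the 13 as a total, "most often" postoperative
complications alongside macrolide trials; the 7 macrolide / 6 complication
split used here is an arbitrary choice within that constraint and nothing
downstream depends on it beyond their sum.

`sample_profile()` draws symptom vectors uniformly inside each category's
defining region (e.g. bacterial: temporal criterion satisfied by one of its
two disjuncts, 3–5 signs; fever, when it is a sign, uniform in
(38, 40.5] °C, otherwise below 38 °C or unrecorded). Chosen once as
clinically plausible ranges and not revisited. Two consequences matter:

- **Round-trip exactness.** Because each region is carved out by the same
  predicates the classifier tests, every non-override sample re-classifies
  to its generating category. Cohort-level percentages are therefore exact
  functions of the counts — which is precisely why reproducing them tests
  the classifier, not the generator: the generator stores no labels in the
  symptom columns.
- **No realism beyond the criteria.** Symptoms are sampled independently;
  there is no correlation structure, no age/sex model, no severity grading,
  no measurement noise. A green cohort test establishes that the engine
  implements the stated criteria, not that it would agree with clinicians
  on real, messy presentations.

**Specialist overrides** model reference decisions made on grounds outside
the engine's inputs (immunosuppression, pre-transplant focus search,
metachronous infection, ...). An override forces the reference label to
antibiotics and records a reason, leaving the symptom vector untouched.
Overrides are drawn uniformly *among patients whose guideline label is not
already antibiotics*: an "override" of a patient the guideline already
sends to antibiotics would change nothing and is not a discrepancy in any
meaningful sense. This makes each of the `k` overrides one discordance, so
concordance on an `n`-patient replica is exactly `(n − k)/n` — with 143
overrides on 1465 patients, the 90.2 % headline figure. That run is an
illustrative reconstruction of the arithmetic, not a recovery of the real
cohort: 143 is simply the discordance count consistent with the published
percentage, which the original study does not print.

## Numerical and formatting choices

- Concordance and percentages are computed as exact ratios of integer
  counts; rounding happens only at the display edge.
- Printed percentages round **half away from zero** (base `round()` is
  half-to-even), 1 decimal within blocks and 2 decimals for the overall
  antibiotic fraction, matching clinical-table convention.
- Generation is reproducible byte-for-byte from `(spec, seed)`; the
  generator saves and restores the caller's RNG state, and the seed is
  recorded as a `# seed:` comment in every cohort file header.
- Degenerate inputs: an all-zero cohort spec yields a header-only file;
  empty label vectors, misaligned patient ids and a missing
  `reference_label` column are errors, not silent zeros.

## Design choices made where the design was open

- The exact decision tree of the original application is not published;
  the tree here is reconstructed from the stated criteria, and the two
  precedence choices above are the only points where reconstruction was
  needed.
- Rule files and cohort specs are JSON rather than YAML: no YAML parser is
  available in the supported dependency set, and JSON loses nothing for
  this schema.
- Therapy classes only — no drug names, doses or durations are modelled,
  because the guideline mapping is stated at the class level.
- `duration_days` is the canonical temporal input; calendar-date parsing
  is deliberately out of scope.

## Limitations

- The knowledge base is the 2012 guideline; severity grading (e.g. VAS
  scores), red-flag complication referral, and the 2020 revision are not
  encoded.
- Concordance on synthetic data is an arithmetic identity once the
  override count is fixed; it says nothing about agreement with clinicians
  on real records, which would require the undeposited original data.
- The engine is deterministic and symbolic; it cannot express the
  probabilistic reasoning some decision-support systems use, and it knows
  nothing a record does not state (comorbidities enter only through the
  override flag).
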