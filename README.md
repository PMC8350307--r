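# eposcds

Rule-based clinical decision support for rhinosinusitis, aimed at the
antibiotic-stewardship problem in primary care: antibiotics help only a
small, well-defined subset of rhinosinusitis patients, yet are prescribed
in the large majority of acute cases. `eposcds` encodes the EPOS 2012
diagnostic criteria as a declarative if–then knowledge base, classifies a
patient presentation with a generic forward-chaining inference engine, and
maps the diagnosis to a guideline therapy class. It also ships a synthetic
cohort generator and an evaluation module, so the whole pipeline — from raw
symptom vectors to cohort-level treatment-distribution and
clinician-concordance statistics — is testable without any patient data.

## The decision rules

With `d` the symptom duration in days, the course is **acute** iff
`d < 84` (12 weeks) and chronic otherwise. For an acute course:

- **Temporal criterion** `T`: `d > 10`, or worsening after day 5.
- **Cardinal signs** `S ∈ [0, 5]`: discoloured/purulent discharge, severe
  local pain, fever `> 38 °C`, raised ESR/CRP, two-stage course
  ("double sickening"). Unknown values never count.

```
acute:    T ∧ S ≥ 3  → ABRS                → antibiotic
          T ∧ S < 3  → post-viral ARS      → decongestant + INCS
          ¬T         → common cold         → decongestant
chronic:  postoperative purulent compl.    → antibiotic
          refractory ∧ no polyps ∧ low IgE → macrolide trial
          otherwise                        → INCS
```

(INCS = intranasal corticosteroid.) The rules live in a JSON file
(`inst/extdata/epos2012_rules.json`) evaluated by a generic monotone
forward chainer, so the knowledge base can be revised — e.g. to EPOS
2020 — without touching code.

## Worked example

```r
library(eposcds)

p <- symptom_profile("p1", duration_days = 14,
                     discoloured_discharge = TRUE, severe_local_pain = TRUE,
                     fever_celsius = 38.6)
d <- infer(p)
d
#> <diagnosis> p1: ABRS  [R1_abrs]
recommend(d)
#> <treatment_plan> ANTIBIOTIC  (antibiotic indicated)
```

A 14-day acute course meets the temporal criterion and shows 3 of the 5
cardinal signs, so the bacterial rule fires and antibiotics are indicated.
At fever 38.0 °C the third sign vanishes (the threshold is strict) and the
same patient is post-viral ARS.

Cohort-level replication of the published retrospective study structure
(1465 synthetic patients; 143 injected specialist overrides):

```r
cmd_replicate_study(seed = 1, override_count = 143)
#> Evaluation report (n = 1465)
#>   concordance: 1322/1465 = 90.2%
#>   acute subcohort (n = 622):
#>     DECONGESTANT               335   53.9%
#>     DECONGESTANT_PLUS_INCS     186   29.9%
#>     ANTIBIOTIC                 101   16.2%
#>   chronic subcohort (n = 843):
#>     INCS                       830   98.5%
#>     ANTIBIOTIC_INDICATED        13    1.5%
#>   overall antibiotic-indicated: 114  7.78%
```

The percentages are computed by re-classifying every synthetic patient from
their raw symptom vector — the generator emits symptoms, not labels — so
they hold only if the rule engine implements the criteria correctly.

## Command line

A thin Rscript front end wraps the same functions:

```sh
script=$(Rscript -e 'cat(system.file("scripts/eposcds.R", package="eposcds"))')
Rscript "$script" simulate --output cohort.csv --preset study_replica --seed 1
Rscript "$script" evaluate --input cohort.csv --output report.json
Rscript "$script" classify --input patients.csv --output recs.csv
Rscript "$script" replicate-study --seed 1 --overrides 143
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch — generates
the study-replica cohort at the given seed, classifies every record,
evaluates concordance with and without the 143 overrides — and writes its
result JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
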