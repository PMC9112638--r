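---
title: "Surveillance intervals, interview flow, and exact audit statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveillance intervals, interview flow, and exact audit statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypsurv)
```

This vignette documents the model behind `polypsurv`: what the rule
engine computes and under which assumptions, how the interview flow is
constructed, how the exact tests are defined numerically, what the
synthetic cohort generator does and does not emulate, and the design
choices made where guidelines or published material left the question
open.

## The rule engine

### Scope

The engine targets the screening population. Three gates precede any
interval computation:

* **Age.** Patients aged 75 or older are out of scope; surveillance
  decisions for older patients are individualized. The boundary is
  *at 75 exactly* (age 75 is out of scope, 74 is in), a choice this
  package fixes and documents because "under 75" and "over 75" phrasing
  is ambiguous at the boundary.
* **Hereditary CRC syndromes and IBD** follow dedicated pathways that
  this tool deliberately does not encode; both return `OUT_OF_SCOPE`.
* **Examination quality.** Guideline intervals presume a complete,
  well-prepared colonoscopy. If the cecum was not reached or preparation
  was inadequate, the engine returns `CASE_BY_CASE` ("repeat/complete
  high-quality examination") rather than an interval it cannot stand
  behind.

### The declarative rule table

All interval knowledge lives in a YAML rule set
(`inst/extdata/ruleset-default.yaml`), hand-transcribed from the CAG
recommendations with USMSTF 2020 filling the post-CRC-resection sequence
and the second-surveillance grid. The engine evaluates *every* index rule
whose predicate matches and combines matched intervals by elementwise
minimum of `(min_months, max_months)`. The guidelines never state a
combination operator for findings that trigger several rows at once;
shortest-interval dominance is the clinically safe reading, and it makes
conservatism monotone: adding a polyp group can only add matching rules
or move counts into tighter bands, so it can never lengthen the result.
The property suite verifies this on seeded random cases.

Predicates are conjunctions over derived findings features. Count
predicates aggregate across histologies the guidelines pool: adenoma
counts pool tubular, tubulovillous/villous, and HGD groups; serrated
counts pool SSP with and without dysplasia. Unknown polyp locations are
treated as proximal, the conservative direction. Intervals are stored in
months so the 6-month post-piecemeal check and the 10-year normal-exam
interval share one scale; rendering in years is display-layer.

Two rows deserve comment. Small rectosigmoid hyperplastic polyps map to
the no-polyp interval (they carry no appreciable risk), while
hyperplastic polyps of 10 mm or more get 3–5 years. Small *proximal*
hyperplastic polyps are not a named category in the transcribed tables;
this package assigns them the small-SSP interval (5–10 years), reading
proximal serrated-appearing lesions conservatively, and ships the row as
`hp_proximal_lt10` so users who disagree can edit one line of YAML. A
piecemeal resection of any lesion of 20 mm or more fires a 6-month rule
that dominates everything through the min-combination.

`load_ruleset()` validates any rule set before use: unique ids, interval
sanity (6–120 months), a complete 3×3 second-surveillance grid, and
*coverage* — every single-group signature on the bucketed grid of
histology × count band × size band × location × resection, plus the
normal exam, must match at least one index rule. A configuration that
silently fails to cover a findings signature is rejected at load time,
not at recommendation time.

### Pathways

* **Index**: first colonoscopy; pure rule-table lookup.
* **Surveillance**: the prior examination is collapsed to a risk class —
  `NORMAL`, `LOW_RISK`, or `HIGH_RISK` (any adenoma ≥ 10 mm,
  villous/HGD histology, ≥ 5 adenomas, SSP ≥ 10 mm, SSP with dysplasia,
  or TSA) — and the (prior, current) class pair keys a 3×3 grid. When
  the current exam is not normal, the grid cell is min-combined with the
  index evaluation of the current findings. The high-risk boundary is
  pinned in code and in the rule file so that tests are deterministic;
  it is configurable per rule set.
* **Post-CRC**: the post-resection sequence 12 → 36 → 60 months keyed by
  how many post-resection colonoscopies the patient has had, tightened
  by any polyp findings through the same min-combination.
* **Family history** is applied last, as a cap (elementwise min):
  60 months for high-risk family history (≥ 2 first-degree relatives
  with CRC, any diagnosed before 60, or an advanced adenoma in a
  relative diagnosed before 60), 120 months for a single relative
  diagnosed at 60 or later. A cap never lengthens a recommendation and
  is idempotent.

Every returned interval satisfies 6 ≤ min ≤ max ≤ 120 months, and the
recommendation object carries all fired rule ids in evaluation order
plus human-readable rationale lines.

## The interview flow

The interview collects only what the dispatched pathway needs. It is a
pure function of the answers so far, so sessions have no hidden state.
Numeric answers are bucketed at rule boundaries (counts 1–2 / 3–4 /
5–10 / > 10; sizes < 10 / ≥ 10 mm, with "piecemeal ≥ 20 mm" as its own
yes/no gate asked only when some lesion was ≥ 10 mm), which makes the
answer alphabet finite and exhaustive path enumeration possible.

The flow is designed to a 4-question minimum and 13-question maximum.
Achieving the 4-question floor required folding: question 1 is the age
band; question 2 combines the hard exclusions (hereditary
syndrome / IBD) with the family-history gate into one four-way choice
(none / hereditary-or-IBD / high-risk FH / lower-risk FH). Had the
family-history gate been a separate question, the shortest in-scope path
(index examination, no polyps) would be 5 questions. The longest path —
surveillance context, prior risk class, adenoma and serrated blocks with
counts and sizes, hyperplastic gate, piecemeal gate — is exactly 13.

`enumerate_interview_paths()` walks all paths (40,490 on the default
flow) and reports the bounds over *in-scope* paths; the eligibility
short-circuits terminate after 1–2 questions with an out-of-scope result
and are tallied separately, since the question-count bounds describe the
interview for patients the tool covers. Finalization assembles a
representative case from the answered bands (representatives sit
strictly inside each band) and calls `recommend()`, so interview/batch
equivalence holds by construction and is asserted over every enumerated
path in the test suite. The interview does not ask about examination
quality; quality gating is available in batch mode, where the caller has
the procedure report in hand.

## Exact tests

For an r×2 table with row margins $R_i$, column margins $(c_1, c_2)$,
and grand total $N$, the conditional probability of a table under fixed
margins is multivariate hypergeometric:

$$P(\mathrm{table}) = \frac{\prod_i \binom{R_i}{n_{i1}}}{\binom{N}{c_1}}.$$

All tables sharing the margins share the denominator, so the
implementation carries each probability as an exact integer numerator.
For every audit-sized table ($N \le 30$, numerators bounded by
$\binom{N}{c_1} \le 1.6\times 10^8$) these integers are exactly
representable in double precision, so tie comparison in the two-sided
sums is exact integer comparison; a $10^{-12}$ relative tolerance is
retained as the documented tie rule. Enumeration is complete and capped
(`max_tables`, default $10^6$); exceeding the cap is an error, never a
silent approximation — there is deliberately no asymptotic fallback, no
Monte-Carlo mode, and no mid-p variant.

Definitions:

* `fisher_2x2(..., "ONE_SIDED_MIN_TAIL")`: the smaller of the lower and
  upper tail probabilities of the top-left cell, inclusive of the
  observed table. Published audit p-values for the 2-group (gender)
  comparisons are reproduced exactly by this convention (0.6300 → 0.63;
  0.50), which is why it is the audit default; the two-sided test is a
  flag away.
* `fisher_2x2(..., "TWO_SIDED")`: total probability of tables no more
  probable than the observed one.
* `freeman_halton()`: the same definition over all r×2 tables with the
  observed margins; on 2 rows it reduces to the two-sided test by
  definition (asserted in tests). The 4-group clinician-type comparison
  evaluates to 0.8636 and the 3-group comparison to 1.0, matching the
  published 0.86 and "> 0.99".

Rows with zero totals (a clinician group absent from one battery) are
dropped before testing. The test suite checks both tests against an
independent enumeration oracle built on sequential `dhyper()` masses, to
$10^{-12}$, on randomized batteries of tables with $N \le 30$, and
cross-checks the two-sided 2×2 case against `stats::fisher.test()`.

## Concordance scoring and audit summaries

A clinician's interval answer is **concordant** when it lies inside the
recommended range, inclusive at both bounds: a range *is* the
recommendation, so naming any point of it is agreement. Answers below
the minimum are `DISCORDANT_SHORTER`, above the maximum (or "no further
colonoscopy" against an interval) `DISCORDANT_LONGER`; a skipped
question counts against the clinician with no direction; out-of-scope
and case-by-case recommendations make a response `NOT_APPLICABLE`. The
five categories partition every audit (asserted as a conservation
property).

Scorecards flag **low scorers** at 50 % or fewer correct, boundary
inclusive (3/7 and 6/12 are low). Grouped summaries build the r×2
low-scorer table, dropping empty groups, and attach the one-sided
min-tail Fisher p-value for two groups or the Freeman–Halton p-value
otherwise. Display percentages round half-up; all comparisons in code
and tests use the underlying fractions.

The pilot-audit summary distinguishes *issue* records — stated agreement
contradicted by chart review (incorrect tool use), age-driven
no-follow-up calls, and cases outside the tool's scope — from clean
records, and reports agreement over all records and over the no-issue
subset, the issue rate, and the shorter/longer split of discordant
records.

## Fixtures and the synthetic cohort

The audit fixtures encode published group-level tables as constants:
grouped low-scorer counts for the 7- and 12-scenario batteries, and the
58-record pilot layout (30 agree / 16 disagree / 4 incorrect tool use /
6 age / 2 out of scope, spread over six endoscopists as 10, 10, 10, 10,
11, 7). Raw per-clinician answers were never published, so the
per-clinician scorecards behind the grouped counts are synthetic,
generated deterministically to match the clinician-type margins, and the
11-shorter/5-longer split of the 16 discordant pilot records is a
documented reconstruction of the published "most (70 %) shorter"
statement (11/16 = 68.75 %). Two published marginals are mutually
inconsistent (the 7-scenario gender row sums to 9 low scorers against a
total of 10), so gender comparisons run on the published gender counts
directly rather than on a joint per-clinician assignment, which cannot
exist.

`generate_cohort()` draws seeded synthetic cases: pathway mixture
(50 % index / 30 % surveillance / 20 % post-CRC), 25 % normal exams,
1–3 polyp groups otherwise with histology, count-band, size-band,
location, and resection weights chosen so that every index rule fires in
a default cohort of 500, plus family-history and exclusion-flag rates
(9 % out-of-scope records). These weights are test scaffolding that
spans the rule space; they are not an epidemiological model of polyp
prevalence, and passing property tests on this cohort demonstrates
engine correctness over the input space, not calibration to any clinical
population. Generation restores the caller's RNG state, so cohorts are
reproducible without side effects.

## Numerical and procedural choices

* Problem sizes: property tests run on cohorts of 300–1000 records and
  oracle batteries of 120–200 tables; exhaustive interview enumeration
  covers all 40,490 paths. The full suite completes in roughly a minute
  on one CPU.
* Seeds are fixed in tests; the acceptance script routes its cohort
  through the `--seed` argument.
* Band representatives in the interview and the coverage grid sit
  strictly inside their buckets (2, 4, 6, 12 for counts; 5, 12, 22 mm
  for sizes), so closed rule bounds treat the representative exactly as
  any member of the band.
* Ties in the min-combination keep all tied rule ids, in configuration
  order.

## Known limitations

* The bundled rule set is a transcription of the public guideline
  tables, not of any proprietary tool's internal logic; wording and
  granularity may differ from deployed decision aids even where the
  recommended intervals agree.
* The flat CSV case format holds at most one polyp group per histology
  (per-histology columns); cases with one histology at two locations
  need the JSON format, and the writer says so rather than merging.
* Age enters only through the ≥ 75 gate; the engine does not shorten or
  lengthen intervals within the screening band, and it does not model
  life-expectancy-based stopping.
* No European guideline variants, no hereditary-syndrome or IBD
  pathways, no EMR integration.
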