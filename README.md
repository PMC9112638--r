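# polypsurv

Guideline-based colonoscopy surveillance intervals, with the audit
machinery to measure how well clinicians agree with them.

## The problem

After a colonoscopy, the patient should be told when to come back. North
American guidelines (the Canadian Association of Gastroenterology, with
the US Multi-Society Task Force filling the scenarios CAG does not
address) key the recommended interval on a large set of factors: the
number, size, histology, location, and resection mode of any polyps on the
current *and* the previous examination, personal history of resected
colorectal cancer, and family history of CRC or advanced adenoma in
first-degree relatives. Clinicians recall and apply these rules
inconsistently — roughly half of audited clinicians match the guidelines
in no more than half of standard scenarios — so a deterministic,
inspectable rule engine is useful both as a point-of-care decision aid and
as the reference key for concordance audits.

`polypsurv` provides:

* **A declarative rule engine.** The guideline table lives in a YAML file
  (`inst/extdata/ruleset-default.yaml`); the engine is interpretation of
  that table. Every matching rule fires, and the final interval is the
  elementwise minimum of the matched ranges — the most conservative
  reading. Dispatch order: eligibility gate (age ≥ 75, hereditary CRC
  syndromes, IBD are out of scope) → examination-quality gate → post-CRC
  pathway → surveillance pathway (keyed by risk class of the prior and
  current exams) → index pathway, with the family-history cap applied
  last.
* **A conditional interview** that asks only the questions the dispatched
  pathway needs: between 4 and 13, verified by exhaustive path
  enumeration, and guaranteed to return the same answer as batch mode.
* **Exact small-table inference.** Fisher's exact test (one-sided
  min-tail and two-sided) and its Freeman–Halton extension to r×2 tables,
  computed by complete enumeration under fixed margins. Probabilities are
  carried as exact integer numerators over the common denominator
  C(N, c₁), so tie detection in the two-sided sums never depends on
  floating-point rounding:

  P(table) = ∏ᵢ C(Rᵢ, nᵢ₁) / C(N, c₁)

* **Concordance auditing**: scoring clinician answers against engine
  output (inclusive interval ranges; shorter/longer discordance
  directions), per-clinician scorecards with the ≤ 50 % low-scorer flag,
  grouped summaries with exact p-values, and pilot-study agreement
  summaries.
* **A seeded synthetic cohort generator** spanning every rule category,
  used by the property tests (determinism, conservatism monotonicity,
  brute-force oracle agreement).

## Worked example

```r
library(polypsurv)

p <- patient_profile(age_years = 55,
                     family_history = family_history(fdr_crc_count = 1,
                                                     youngest_dx_age = 52))
f <- colonoscopy_findings(list(
  polyp_group("TUBULAR_ADENOMA", count = 1, max_size_mm = 12),
  polyp_group("TUBULAR_ADENOMA", count = 2, max_size_mm = 5)))
recommend(p, f)
#> <recommendation> INTERVAL: repeat in 3 y [36, 36] months
#>   rules: adenoma_ge10mm
#>   - index pathway: 3 y (rules adenoma_ge10mm)
```

Three tubular adenomas, the largest 12 mm: the ≥ 10 mm rule (3 years)
dominates the 3–4-small-adenoma rule (3–5 years) under the
most-conservative combination, and the high-risk family history cap
(5 years) does not bind because the base is already tighter. A normal
examination in the same patient returns `[60, 60]` — the 10-year no-polyp
interval capped at 5 years by the family history.

The same answer through the interview:

```r
s <- interview_start()
for (qa in list(c("age_band", "under_75"), c("exclusions_fh", "none"),
                c("context", "first_colonoscopy"), c("polyps", "no")))
  s <- interview_submit(s, qa[1], qa[2])
interview_finalize(s)$recommendation
#> <recommendation> INTERVAL: repeat in 10 y [120, 120] months
#>   rules: no_polyps
#>   - index pathway: 10 y (rules no_polyps)
```

Exact tests on an audit table (male vs female low scorers, 6/13 vs 3/6):

```r
fisher_2x2(rbind(c(6, 7), c(3, 3)))
#> [1] 0.630031
freeman_halton(rbind(c(2, 3), c(2, 2), c(3, 1), c(3, 3)))
#> [1] 0.8636039
```

A command-line front end with `recommend`, `interview`, `evaluate`,
`stats`, `simulate`, and `fixtures` subcommands is installed at
`inst/cli/polypsurv`:

```sh
$(Rscript -e 'cat(system.file("cli", "polypsurv", package = "polypsurv"))') \
  stats --table "6,7;3,3"
```

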