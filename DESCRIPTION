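Package: polypsurv
Title: Guideline-Based Colonoscopy Surveillance Intervals and Concordance Audits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative rule engine that maps a patient's colonoscopy
    findings (polyp histology, number, size, location, resection mode),
    personal history of colorectal cancer and family history onto the
    surveillance interval recommended by North American guidelines (CAG,
    with USMSTF filling the post-resection and second-surveillance gaps).
    Includes a conditional interview flow that collects only the inputs the
    dispatched pathway needs (4 to 13 questions), exact inference on small
    r-by-2 contingency tables (Fisher's exact test and its Freeman-Halton
    extension, by complete enumeration under fixed margins), concordance
    scoring of clinician recommendations against the engine, pilot-audit
    summaries, and a seeded synthetic cohort generator spanning the rule
    space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
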