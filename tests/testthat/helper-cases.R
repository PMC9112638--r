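# shared builders for engine tests

pg <- function(hist, count = 1L, size = 5L, loc = "PROXIMAL",
               res = "COMPLETE_ENBLOC") {
  polyp_group(hist, count, size, loc, res)
}

exam <- function(..., cecum = TRUE, prep = TRUE, ordinal = "INDEX") {
  colonoscopy_findings(list(...), cecum_reached = cecum,
                       prep_adequate = prep, ordinal = ordinal)
}

pt <- function(age = 55L, ...) patient_profile(age_years = age, ...)

iv_of <- function(rec) c(rec$interval$min_months, rec$interval$max_months)

# drive a whole interview from a named answer list
run_interview <- function(answers, ruleset = RS) {
  s <- interview_start()
  for (id in names(answers)) s <- interview_submit(s, id, answers[[id]])
  interview_finalize(s, ruleset)
}

RS <- load_ruleset()
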