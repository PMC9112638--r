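test_that("eligibility gate fires on age, hereditary syndrome, and IBD", {
  rec <- check_eligibility(pt(80))
  expect_equal(rec$status, "OUT_OF_SCOPE")
  expect_match(rec$rationale, "age >= 75", all = FALSE)
  expect_equal(check_eligibility(pt(55, hereditary_syndrome = TRUE))$status,
               "OUT_OF_SCOPE")
  expect_equal(check_eligibility(pt(55, ibd = TRUE))$status, "OUT_OF_SCOPE")
  expect_null(check_eligibility(pt(55)))
  expect_equal(check_eligibility(pt(75))$status, "OUT_OF_SCOPE") # boundary
  expect_null(check_eligibility(pt(74)))
})

test_that("risk classification follows the high-risk findings list", {
  expect_equal(classify_risk(exam()), "NORMAL")
  expect_equal(classify_risk(exam(pg("TUBULAR_ADENOMA", 1, 12))),
               "HIGH_RISK")
  expect_equal(classify_risk(exam(pg("TUBULAR_ADENOMA", 2, 5))), "LOW_RISK")
  expect_equal(classify_risk(exam(pg("TUBULOVILLOUS_OR_VILLOUS", 1, 5))),
               "HIGH_RISK")
  expect_equal(classify_risk(exam(pg("TUBULAR_ADENOMA", 5, 4))),
               "HIGH_RISK")
  expect_equal(classify_risk(exam(pg("SSP_DYSPLASIA", 1, 4))), "HIGH_RISK")
  expect_equal(classify_risk(exam(pg("TSA", 1, 4))), "HIGH_RISK")
  expect_equal(classify_risk(exam(pg("SSP", 2, 6))), "LOW_RISK")
  expect_equal(classify_risk(exam(pg("HYPERPLASTIC", 3, 6))), "LOW_RISK")
})

test_that("index pathway reproduces the default rule table lookups", {
  expect_equal(iv_of(recommend_index(pt(), exam(), RS)), c(120, 120))
  expect_equal(iv_of(recommend_index(pt(), exam(pg("SSP", 2, 6)), RS)),
               c(60, 120))
  # 1 large + 2 small tubular adenomas: most conservative of 3 y and 7-10 y
  rec <- recommend_index(pt(), exam(pg("TUBULAR_ADENOMA", 1, 12),
                                    pg("TUBULAR_ADENOMA", 2, 5)), RS)
  expect_equal(iv_of(rec), c(36, 36))
  # piecemeal resection of a large lesion dominates everything
  rec <- recommend_index(pt(), exam(pg("TUBULAR_ADENOMA", 2, 22,
                                       res = "PIECEMEAL")), RS)
  expect_equal(iv_of(rec), c(6, 6))
  expect_true("piecemeal_ge20mm" %in% rec$fired_rule_ids)
  # rectosigmoid hyperplastic < 10 mm maps to the no-polyp interval
  expect_equal(iv_of(recommend_index(pt(), exam(pg("HYPERPLASTIC", 2, 5,
                                                   loc = "RECTOSIGMOID")),
                                     RS)), c(120, 120))
  expect_equal(iv_of(recommend_index(pt(), exam(pg("HYPERPLASTIC", 1, 12)),
                                     RS)), c(36, 60))
})

test_that("surveillance pathway keys on (prior, current) risk classes", {
  high <- exam(pg("TUBULAR_ADENOMA", 1, 12))
  low <- exam(pg("TUBULAR_ADENOMA", 1, 5))
  expect_equal(iv_of(recommend_surveillance(pt(), high, exam(), RS)),
               c(60, 60))
  expect_equal(iv_of(recommend_surveillance(pt(), low, exam(), RS)),
               c(120, 120))
  expect_equal(iv_of(recommend_surveillance(pt(), high, high, RS)),
               c(36, 36))
  # non-normal current is tightened by the index rules
  rec <- recommend_surveillance(pt(), high, exam(pg("SSP_DYSPLASIA", 1, 5)),
                                RS)
  expect_equal(iv_of(rec), c(36, 36))
  expect_true("step_HIGH_RISK_HIGH_RISK" %in% rec$fired_rule_ids)
  expect_true("ssp_dysplasia" %in% rec$fired_rule_ids)
})

test_that("post-CRC sequence runs 12, 36, then 60 months, tightened by findings", {
  p0 <- pt(crc_history = TRUE, months_since_crc_resection = 3,
           post_resection_colonoscopy_count = 0)
  p1 <- pt(crc_history = TRUE, months_since_crc_resection = 15,
           post_resection_colonoscopy_count = 1)
  p2 <- pt(crc_history = TRUE, months_since_crc_resection = 50,
           post_resection_colonoscopy_count = 2)
  expect_equal(iv_of(recommend_post_crc(p0, exam(), RS)), c(12, 12))
  expect_equal(iv_of(recommend_post_crc(p1, exam(), RS)), c(36, 36))
  expect_equal(iv_of(recommend_post_crc(p2, exam(), RS)), c(60, 60))
  expect_equal(iv_of(recommend_post_crc(
    p2, exam(pg("ADENOMA_HGD", 1, 5)), RS)), c(36, 36))
  expect_error(recommend_post_crc(pt(), exam(), RS), "crc_history")
})

test_that("family-history caps bind elementwise and only when tighter", {
  base <- recommend_index(pt(), exam(), RS) # [120, 120]
  expect_equal(iv_of(apply_family_history(base, family_history(1, 52),
                                          ruleset = RS)), c(60, 60))
  expect_equal(iv_of(apply_family_history(base, family_history(2, 70),
                                          ruleset = RS)), c(60, 60))
  expect_equal(iv_of(apply_family_history(
    base, family_history(0, 55, fdr_advanced_adenoma = TRUE),
    ruleset = RS)), c(60, 60))
  # a cap larger than the base leaves the base untouched
  tight <- recommend_index(pt(), exam(pg("ADENOMA_HGD", 1, 5)), RS)
  expect_identical(apply_family_history(tight, family_history(1, 52),
                                        ruleset = RS)$interval,
                   tight$interval)
  # single relative diagnosed at >= 60: 120-month cap (no-op on 10 y)
  expect_equal(iv_of(apply_family_history(base, family_history(1, 65),
                                          ruleset = RS)), c(120, 120))
  expect_identical(apply_family_history(base, family_history(),
                                        ruleset = RS), base)
})

test_that("dispatcher routes pathways and applies the FH cap last", {
  expect_equal(recommend(pt(80), exam(), ruleset = RS)$status,
               "OUT_OF_SCOPE")
  expect_equal(iv_of(recommend(pt(), exam(), ruleset = RS)), c(120, 120))
  p0 <- pt(crc_history = TRUE, months_since_crc_resection = 3)
  expect_equal(iv_of(recommend(p0, exam(), ruleset = RS)), c(12, 12))
  fhp <- pt(family_history = family_history(2, 55))
  rec <- recommend(fhp, exam(), ruleset = RS)
  expect_equal(iv_of(rec), c(60, 60))
  expect_equal(rec$fired_rule_ids, c("no_polyps", "fh_high_risk_cap"))
})

test_that("incomplete or poorly prepared examinations are case-by-case", {
  rec <- recommend(pt(), exam(cecum = FALSE), ruleset = RS)
  expect_equal(rec$status, "CASE_BY_CASE")
  expect_match(rec$rationale, "high-quality", all = FALSE)
  expect_equal(recommend(pt(), exam(prep = FALSE), ruleset = RS)$status,
               "CASE_BY_CASE")
})
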