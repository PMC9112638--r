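rec_3_5y <- recommend_index(pt(), exam(pg("TUBULAR_ADENOMA", 3, 5)), RS)
rec_5y <- recommend_surveillance(pt(), exam(pg("ADENOMA_HGD", 1, 5)),
                                 exam(), RS)
rec_5_10y <- recommend_index(pt(), exam(pg("SSP", 2, 6)), RS)

test_that("responses are scored inclusively against interval ranges", {
  expect_equal(score_response(60, rec_3_5y), "CONCORDANT")  # upper bound
  expect_equal(score_response(36, rec_3_5y), "CONCORDANT")  # lower bound
  expect_equal(score_response(36, rec_5y), "DISCORDANT_SHORTER")
  expect_equal(score_response(12, rec_5_10y), "DISCORDANT_SHORTER")
  expect_equal(score_response(120, rec_3_5y), "DISCORDANT_LONGER")
  expect_equal(score_response("NO_FURTHER", rec_3_5y), "DISCORDANT_LONGER")
  expect_equal(score_response("SKIPPED", rec_3_5y),
               "DISCORDANT_NO_DIRECTION")
  expect_equal(score_response(60, recommend(pt(80), exam(), ruleset = RS)),
               "NOT_APPLICABLE")
  expect_error(score_response(-3, rec_3_5y), "positive")
})

test_that("score categories always partition an audit (conservation)", {
  set.seed(77)
  key <- list(a = rec_3_5y, b = rec_5y, c = rec_5_10y,
              d = recommend(pt(80), exam(), ruleset = RS))
  answers <- c(12, 36, 48, 60, 120, NA)
  n <- 120L
  resp <- data.frame(
    clinician_id = sample(paste0("c", 1:12), n, replace = TRUE),
    group = "GASTROENTEROLOGIST",
    scenario_id = sample(names(key), n, replace = TRUE),
    stringsAsFactors = FALSE)
  resp$answer <- lapply(seq_len(n), function(i) {
    a <- sample(answers, 1)
    if (is.na(a)) sample(c("SKIPPED", "NO_FURTHER"), 1) else a
  })
  scores <- vapply(seq_len(n), function(i)
    score_response(resp$answer[[i]], key[[resp$scenario_id[i]]]), "")
  expect_true(all(scores %in% polypsurv:::SCORE_LEVELS))
  tab <- table(factor(scores, levels = polypsurv:::SCORE_LEVELS))
  expect_equal(sum(tab), n)
})

test_that("scorecards count concordant answers and flag low scorers at 50%", {
  key <- list(s1 = rec_3_5y, s2 = rec_5y)
  resp <- data.frame(
    clinician_id = rep(c("good", "mid", "bad"), each = 2),
    group = rep(c("PCP", "PCP", "SURGEON"), each = 2),
    scenario_id = rep(c("s1", "s2"), 3),
    stringsAsFactors = FALSE)
  resp$answer <- list(48, 60, 48, 12, 120, 12)
  sc <- build_scorecards(resp, key)
  sc <- sc[order(sc$clinician_id), ]
  expect_equal(sc$n_correct, c(0L, 2L, 1L)) # bad, good, mid
  expect_equal(sc$low_scorer, c(TRUE, FALSE, TRUE)) # 50% boundary is low
  expect_error(build_scorecards(
    data.frame(clinician_id = "x", group = "PCP", scenario_id = "nope",
               answer = I(list(60))), key), "unknown scenario")
})

test_that("low-scorer summary picks the exact test by group count", {
  fx <- table2_fixture()
  s <- low_scorer_summary(fx$scorecards_7, "CLINICIAN_TYPE")
  expect_equal(s$n_low, 10L)
  expect_equal(s$n_total, 19L)
  expect_equal(s$percent, 53)
  expect_equal(s$method, "freeman_halton")
  g <- low_scorer_summary(fx$gender_7)
  expect_equal(g$method, "fisher_one_sided_min_tail")
  expect_equal(round(g$p_value, 2), 0.63)
})

test_that("pilot summary recomputes its own percentages exactly", {
  ps <- pilot_summary(table3_fixture())
  expect_equal(ps$n, 58L)
  expect_equal(ps$n_agree, 30L)
  expect_equal(ps$n_issues, 12L)
  expect_equal(ps$agreement_all_pct,
               polypsurv:::round_half_up(100 * ps$n_agree / ps$n))
  expect_equal(ps$agreement_no_issue_pct,
               polypsurv:::round_half_up(100 * ps$n_agree / ps$n_no_issue))
  expect_equal(ps$issue_rate, ps$n_issues / ps$n)
  # all-agree, no exclusions
  clean <- data.frame(endoscopist_id = "E1", stated_agreement = TRUE,
                      chart_review_agreement = TRUE, exclusion = "NONE",
                      direction = NA_character_, would_change = NA)
  expect_equal(pilot_summary(clean)$agreement_all_pct, 100)
})

test_that("direction breakdown covers discordant items only", {
  db <- direction_breakdown(table3_fixture()$direction)
  expect_equal(db$n, 16L)
  expect_equal(db$n_shorter, 11L)
  expect_equal(db$shorter, 11 / 16)
  expect_equal(direction_breakdown(scenario_direction_fixture())$longer_pct,
               58)
  empty <- direction_breakdown(rep(NA_character_, 5))
  expect_equal(empty$n, 0L)
})
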