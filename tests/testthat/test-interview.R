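test_that("a session starts empty with the age question pending", {
  s <- interview_start()
  q <- interview_next_question(s)
  expect_s3_class(q, "interview_question")
  expect_equal(q$id, "age_band")
  expect_length(s$answers, 0L)
  expect_error(interview_finalize(s, RS), "incomplete")
})

test_that("eligibility answers short-circuit to an out-of-scope result", {
  fin <- run_interview(list(age_band = "75_or_older"))
  expect_equal(fin$recommendation$status, "OUT_OF_SCOPE")
  expect_equal(fin$path_length, 1L)
  fin <- run_interview(list(age_band = "under_75",
                            exclusions_fh = "hereditary_or_ibd"))
  expect_equal(fin$recommendation$status, "OUT_OF_SCOPE")
  expect_equal(fin$path_length, 2L)
})

test_that("answers are validated and must follow the pending question", {
  s <- interview_start()
  expect_error(interview_submit(s, "polyps", "yes"), "out-of-order")
  expect_error(interview_submit(s, "age_band", "eighty"), "must be one of")
  s <- interview_submit(s, "age_band", "under_75")
  expect_equal(interview_next_question(s)$id, "exclusions_fh")
})

test_that("pathway-specific questions appear only on their pathway", {
  s <- interview_start()
  s <- interview_submit(s, "age_band", "under_75")
  s <- interview_submit(s, "exclusions_fh", "none")
  s <- interview_submit(s, "context", "post_crc_resection")
  expect_equal(interview_next_question(s)$id, "post_crc_count")
  s2 <- interview_start()
  s2 <- interview_submit(s2, "age_band", "under_75")
  s2 <- interview_submit(s2, "exclusions_fh", "none")
  s2 <- interview_submit(s2, "context", "surveillance")
  expect_equal(interview_next_question(s2)$id, "prior_risk")
})

test_that("the shortest interview is 4 questions and matches batch mode", {
  fin <- run_interview(list(age_band = "under_75", exclusions_fh = "none",
                            context = "first_colonoscopy", polyps = "no"))
  expect_equal(fin$path_length, 4L)
  expect_equal(iv_of(fin$recommendation), c(120, 120))
  expect_identical(fin$recommendation,
                   recommend(fin$inputs$profile, fin$inputs$current,
                             fin$inputs$prior, RS))
})

test_that("the longest interview is 13 questions", {
  fin <- run_interview(list(
    age_band = "under_75", exclusions_fh = "fh_high_risk",
    context = "surveillance", prior_risk = "high_risk", polyps = "yes",
    adenoma = "villous_component", adenoma_count = "3_4",
    adenoma_size = "10mm_or_more", serrated = "ssp",
    serrated_count = "1_2", serrated_size = "under_10mm",
    hyperplastic = "none", piecemeal = "yes"))
  expect_equal(fin$path_length, 13L)
  expect_equal(iv_of(fin$recommendation), c(6, 6))
  expect_true("piecemeal_ge20mm" %in%
                fin$recommendation$fired_rule_ids)
})

test_that("exhaustive enumeration bounds the flow at 4-13 questions", {
  en <- enumerate_interview_paths(RS, check_equivalence = TRUE)
  expect_true(en$all_terminate)
  expect_equal(en$min_questions, 4L)
  expect_equal(en$max_questions, 13L)
  expect_true(all(en$path_lengths >= 4L & en$path_lengths <= 13L))
  expect_setequal(en$short_circuit_lengths, c(1L, 2L))
  # no dead questions: every id is reachable on some path
  expect_setequal(en$questions_seen, names(polypsurv:::INTERVIEW_QUESTIONS))
  expect_gt(en$n_paths, 1000L)
})
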