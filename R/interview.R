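# Conditional question sequence. The flow is a pure function of the answers
# given so far: interview_next_question() recomputes the pending question
# from scratch, so a session has no hidden state and identical answer
# scripts always take identical paths.
#
# Numeric answers are bucketed at the rule boundaries (counts 1-2 / 3-4 /
# 5-10 / >10; sizes <10 / >=10 mm, with piecemeal-of->=20mm as its own
# gate), which keeps the answer alphabet -- and therefore exhaustive path
# enumeration -- finite. Eligibility and the family-history gate are folded
# into the first two questions so the shortest complete interview is 4
# questions; the longest is 13.

INTERVIEW_QUESTIONS <- list(
  age_band = list(
    prompt = "Patient age?",
    choices = c("under_75", "75_or_older")),
  exclusions_fh = list(
    prompt = paste("Any of: hereditary CRC syndrome or IBD; family history",
                   "of CRC/advanced adenoma in a first-degree relative?"),
    choices = c("none", "hereditary_or_ibd", "fh_high_risk", "fh_low_risk")),
  context = list(
    prompt = "What kind of colonoscopy is this?",
    choices = c("first_colonoscopy", "surveillance", "post_crc_resection")),
  post_crc_count = list(
    prompt = "Completed post-resection colonoscopies before this one?",
    choices = c("0", "1", "2_or_more")),
  prior_risk = list(
    prompt = "Findings of the prior colonoscopy?",
    choices = c("normal", "low_risk", "high_risk")),
  polyps = list(
    prompt = "Were any polyps found?", choices = c("yes", "no")),
  adenoma = list(
    prompt = "Adenomas found? Worst histology?",
    choices = c("none", "tubular", "villous_component",
                "high_grade_dysplasia")),
  adenoma_count = list(
    prompt = "Total number of adenomas?",
    choices = c("1_2", "3_4", "5_10", "over_10")),
  adenoma_size = list(
    prompt = "Largest adenoma?",
    choices = c("under_10mm", "10mm_or_more")),
  serrated = list(
    prompt = "Serrated lesions found? Worst histology?",
    choices = c("none", "ssp", "ssp_dysplasia", "tsa")),
  serrated_count = list(
    prompt = "Number of sessile serrated polyps?",
    choices = c("1_2", "3_4", "5_10", "over_10")),
  serrated_size = list(
    prompt = "Largest sessile serrated polyp?",
    choices = c("under_10mm", "10mm_or_more")),
  hyperplastic = list(
    prompt = "Hyperplastic polyps?",
    choices = c("none", "under_10mm_rectosigmoid", "under_10mm_proximal",
                "10mm_or_more")),
  piecemeal = list(
    prompt = "Was a lesion of 20 mm or more removed piecemeal?",
    choices = c("yes", "no")))

make_question <- function(id) {
  q <- INTERVIEW_QUESTIONS[[id]]
  structure(list(id = id, prompt = q$prompt, answer_kind = "CHOICE",
                 choices = q$choices),
            class = "interview_question")
}

#' @export
print.interview_question <- function(x, ...) {
  cat("[", x$id, "] ", x$prompt, "\n  (",
      paste(x$choices, collapse = " / "), ")\n", sep = "")
  invisible(x)
}

#' Start an interview session
#'
#' @return An empty `interview_session`.
#' @examples
#' s <- interview_start()
#' interview_next_question(s)
#' @export
interview_start <- function() {
  structure(list(answers = list()), class = "interview_session")
}

# The flow definition: next question id, or a terminal marker, given the
# answers so far.
flow_next <- function(ans) {
  get1 <- function(id) ans[[id]]
  if (is.null(get1("age_band"))) return("age_band")
  if (get1("age_band") == "75_or_older")
    return(list(terminal = TRUE, short_circuit = "age"))
  if (is.null(get1("exclusions_fh"))) return("exclusions_fh")
  if (get1("exclusions_fh") == "hereditary_or_ibd")
    return(list(terminal = TRUE, short_circuit = "exclusion"))
  if (is.null(get1("context"))) return("context")
  if (get1("context") == "post_crc_resection" &&
      is.null(get1("post_crc_count"))) return("post_crc_count")
  if (get1("context") == "surveillance" && is.null(get1("prior_risk")))
    return("prior_risk")
  if (is.null(get1("polyps"))) return("polyps")
  if (get1("polyps") == "no")
    return(list(terminal = TRUE, short_circuit = NA_character_))
  if (is.null(get1("adenoma"))) return("adenoma")
  if (get1("adenoma") != "none") {
    if (is.null(get1("adenoma_count"))) return("adenoma_count")
    if (is.null(get1("adenoma_size"))) return("adenoma_size")
  }
  if (is.null(get1("serrated"))) return("serrated")
  if (get1("serrated") == "ssp") {
    if (is.null(get1("serrated_count"))) return("serrated_count")
    if (is.null(get1("serrated_size"))) return("serrated_size")
  }
  if (is.null(get1("hyperplastic"))) return("hyperplastic")
  any_large <- identical(get1("adenoma_size"), "10mm_or_more") ||
    identical(get1("serrated_size"), "10mm_or_more") ||
    identical(get1("hyperplastic"), "10mm_or_more")
  if (any_large && is.null(get1("piecemeal"))) return("piecemeal")
  list(terminal = TRUE, short_circuit = NA_character_)
}

#' Next question of a session
#'
#' @param state An `interview_session`.
#' @return The pending `interview_question`, or a terminal marker (a list
#'   with `terminal = TRUE`) when the collected answers suffice.
#' @export
interview_next_question <- function(state) {
  stopifnot(inherits(state, "interview_session"))
  nxt <- flow_next(state$answers)
  if (is.character(nxt)) make_question(nxt) else nxt
}

#' Record an answer
#'
#' @param state An `interview_session`.
#' @param question_id Must be the id of the currently pending question;
#'   answering out of order is an error.
#' @param answer One of the pending question's choices.
#' @return The grown `interview_session`.
#' @export
interview_submit <- function(state, question_id, answer) {
  stopifnot(inherits(state, "interview_session"))
  nxt <- flow_next(state$answers)
  if (!is.character(nxt))
    fail("the interview is complete; no question is pending")
  if (!identical(question_id, nxt))
    fail("out-of-order answer: pending question is '", nxt, "', got '",
         question_id, "'")
  choices <- INTERVIEW_QUESTIONS[[question_id]]$choices
  if (!is.character(answer) || length(answer) != 1L ||
      !answer %in% choices)
    fail("answer to '", question_id, "' must be one of: ",
         paste(choices, collapse = ", "))
  state$answers[[question_id]] <- answer
  state
}

# Representative inputs for a completed answer set. Band representatives sit
# strictly inside each bucket, so the assembled case is a faithful witness
# of the answered bands.
assemble_interview_inputs <- function(ans) {
  count_rep <- c(`1_2` = 2L, `3_4` = 4L, `5_10` = 6L, over_10 = 12L)
  age <- if (identical(ans$age_band, "75_or_older")) 80L else 60L
  hereditary <- identical(ans$exclusions_fh, "hereditary_or_ibd")
  fh <- switch(ans$exclusions_fh %||% "none",
               fh_high_risk = family_history(2L, 55L),
               fh_low_risk = family_history(1L, 65L),
               family_history())
  crc <- identical(ans$context, "post_crc_resection")
  n_post <- switch(ans$post_crc_count %||% "0",
                   `0` = 0L, `1` = 1L, `2_or_more` = 2L)
  profile <- patient_profile(
    age_years = age, crc_history = crc,
    months_since_crc_resection = if (crc) 6L else NA,
    post_resection_colonoscopy_count = n_post,
    family_history = fh, hereditary_syndrome = hereditary, ibd = FALSE)

  prior <- NULL
  if (identical(ans$context, "surveillance"))
    prior <- switch(ans$prior_risk,
                    normal = colonoscopy_findings(),
                    low_risk = colonoscopy_findings(list(
                      polyp_group("TUBULAR_ADENOMA", 1L, 5L))),
                    high_risk = colonoscopy_findings(list(
                      polyp_group("TUBULAR_ADENOMA", 1L, 12L))))

  groups <- list()
  piecemeal_pending <- identical(ans$piecemeal, "yes")
  add_group <- function(histology, count, large, location = "PROXIMAL") {
    size <- if (!large) 5L
    else if (piecemeal_pending) { piecemeal_pending <<- FALSE; 22L }
    else 12L
    polyp_group(histology, count, size, location,
                resection = if (size >= 20L) "PIECEMEAL"
                else "COMPLETE_ENBLOC")
  }
  if (identical(ans$polyps, "yes")) {
    if (!is.null(ans$adenoma) && ans$adenoma != "none") {
      hist <- switch(ans$adenoma, tubular = "TUBULAR_ADENOMA",
                     villous_component = "TUBULOVILLOUS_OR_VILLOUS",
                     high_grade_dysplasia = "ADENOMA_HGD")
      groups <- c(groups, list(add_group(
        hist, count_rep[[ans$adenoma_count]],
        identical(ans$adenoma_size, "10mm_or_more"))))
    }
    if (!is.null(ans$serrated) && ans$serrated != "none") {
      if (ans$serrated == "ssp")
        groups <- c(groups, list(add_group(
          "SSP", count_rep[[ans$serrated_count]],
          identical(ans$serrated_size, "10mm_or_more"))))
      else groups <- c(groups, list(add_group(
        toupper(sub("ssp_dysplasia", "SSP_DYSPLASIA", ans$serrated)),
        1L, FALSE)))
    }
    if (!is.null(ans$hyperplastic) && ans$hyperplastic != "none")
      groups <- c(groups, list(switch(
        ans$hyperplastic,
        under_10mm_rectosigmoid = add_group("HYPERPLASTIC", 1L, FALSE,
                                            "RECTOSIGMOID"),
        under_10mm_proximal = add_group("HYPERPLASTIC", 1L, FALSE),
        `10mm_or_more` = add_group("HYPERPLASTIC", 1L, TRUE))))
  }
  current <- colonoscopy_findings(groups,
                                  ordinal = if (is.null(prior)) "INDEX"
                                  else "SURVEILLANCE")
  list(profile = profile, prior = prior, current = current)
}

#' Finish a session and obtain the recommendation
#'
#' Assembles the profile and findings implied by the recorded answers and
#' runs [recommend()] on them, so the interview result is identical to
#' batch mode on the same inputs by construction.
#'
#' @param state A completed `interview_session`.
#' @param ruleset A [load_ruleset()] result.
#' @return A list with `recommendation`, `path_length` (questions asked),
#'   and the assembled `inputs`.
#' @export
interview_finalize <- function(state, ruleset = load_ruleset()) {
  stopifnot(inherits(state, "interview_session"))
  nxt <- flow_next(state$answers)
  if (is.character(nxt))
    fail("incomplete session: question '", nxt, "' is still pending")
  inputs <- assemble_interview_inputs(state$answers)
  rec <- recommend(inputs$profile, inputs$current, inputs$prior, ruleset)
  list(recommendation = rec, path_length = length(state$answers),
       inputs = inputs)
}

#' Exhaustively enumerate every interview path
#'
#' Walks the finite answer alphabet depth-first through
#' [interview_next_question()] / [interview_submit()] and finalizes each
#' complete path. Question-count bounds are reported over in-scope paths;
#' the eligibility short-circuits (which terminate after one or two
#' questions with an out-of-scope result) are tallied separately.
#'
#' @param ruleset A [load_ruleset()] result.
#' @param check_equivalence Also recompute each path's recommendation in
#'   batch mode and verify identity (slower; used by the test suite).
#' @return A list: `n_paths`, `min_questions`, `max_questions` (in-scope),
#'   `short_circuit_lengths`, `all_terminate`, `questions_seen`,
#'   `path_lengths`.
#' @export
enumerate_interview_paths <- function(ruleset = load_ruleset(),
                                      check_equivalence = FALSE) {
  lens <- integer()
  sc_lens <- integer()
  seen <- character()
  n_paths <- 0L
  walk <- function(state, depth) {
    if (depth > 20L) fail("interview flow failed to terminate")
    nxt <- interview_next_question(state)
    if (!inherits(nxt, "interview_question")) {
      n_paths <<- n_paths + 1L
      fin <- interview_finalize(state, ruleset)
      if (check_equivalence) {
        again <- recommend(fin$inputs$profile, fin$inputs$current,
                           fin$inputs$prior, ruleset)
        if (!identical(fin$recommendation, again))
          fail("interview/batch mismatch on a path")
      }
      if (!is.na(nxt$short_circuit)) sc_lens <<- c(sc_lens, fin$path_length)
      else lens <<- c(lens, fin$path_length)
      return(invisible())
    }
    seen <<- union(seen, nxt$id)
    for (a in nxt$choices)
      walk(interview_submit(state, nxt$id, a), depth + 1L)
    invisible()
  }
  walk(interview_start(), 0L)
  list(n_paths = n_paths, min_questions = min(lens),
       max_questions = max(lens), short_circuit_lengths = sc_lens,
       all_terminate = TRUE, questions_seen = seen, path_lengths = lens)
}
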