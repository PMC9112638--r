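# Concordance scoring of clinician recommendations against engine output,
# and the grouped audit summaries (low-scorer tables, pilot agreement).

SCORE_LEVELS <- c("CONCORDANT", "DISCORDANT_SHORTER", "DISCORDANT_LONGER",
                  "DISCORDANT_NO_DIRECTION", "NOT_APPLICABLE")

# display percentages round half-up, matching "53%", "65%"
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Score one clinician answer against a recommendation
#'
#' An interval answer is concordant when it lies inside the recommended
#' range, inclusive at both bounds (a "5 years" answer agrees with a
#' "3-5 years" recommendation); shorter/longer discordance is relative to
#' the range bounds. A skipped question is incorrect with no direction.
#' Recommendations without an interval to compare against (out of scope,
#' case by case) make the response not applicable.
#'
#' @param answer A number of months, or `"NO_FURTHER"`, or `"SKIPPED"`.
#' @param recommendation A `recommendation` from the engine.
#' @return One of `"CONCORDANT"`, `"DISCORDANT_SHORTER"`,
#'   `"DISCORDANT_LONGER"`, `"DISCORDANT_NO_DIRECTION"`,
#'   `"NOT_APPLICABLE"`.
#' @examples
#' rec <- recommend(patient_profile(55), colonoscopy_findings())
#' score_response(120, rec)
#' score_response(36, rec)
#' @export
score_response <- function(answer, recommendation) {
  stopifnot(inherits(recommendation, "recommendation"))
  if (recommendation$status %in% c("OUT_OF_SCOPE", "CASE_BY_CASE"))
    return("NOT_APPLICABLE")
  if (identical(answer, "SKIPPED")) return("DISCORDANT_NO_DIRECTION")
  if (identical(answer, "NO_FURTHER")) {
    return(if (recommendation$status == "NO_FURTHER") "CONCORDANT"
           else "DISCORDANT_LONGER")
  }
  if (!is.numeric(answer) || length(answer) != 1L || is.na(answer) ||
      answer <= 0)
    fail("answer must be a positive number of months, 'NO_FURTHER', or ",
         "'SKIPPED'")
  if (recommendation$status == "NO_FURTHER") return("DISCORDANT_SHORTER")
  iv <- recommendation$interval
  if (answer < iv$min_months) "DISCORDANT_SHORTER"
  else if (answer > iv$max_months) "DISCORDANT_LONGER"
  else "CONCORDANT"
}

#' Per-clinician scorecards
#'
#' @param responses Data frame with columns `clinician_id`, `group`,
#'   `scenario_id`, `answer` (months as numeric, or `"NO_FURTHER"` /
#'   `"SKIPPED"`), and optionally `gender`.
#' @param key Named list mapping scenario ids to engine `recommendation`s.
#' @return Data frame with one row per clinician: `n_correct`,
#'   `n_scenarios` (applicable scenarios), ratio and the `low_scorer` flag
#'   (at most 50 percent correct, boundary inclusive).
#' @export
build_scorecards <- function(responses, key) {
  stopifnot(is.data.frame(responses))
  missing_scn <- setdiff(unique(responses$scenario_id), names(key))
  if (length(missing_scn))
    fail("unknown scenario id(s): ", paste(missing_scn, collapse = ", "))
  scores <- vapply(seq_len(nrow(responses)), function(i) {
    a <- responses$answer[[i]]
    if (is.character(a) && !a %in% c("NO_FURTHER", "SKIPPED"))
      a <- as.numeric(a)
    score_response(a, key[[responses$scenario_id[[i]]]])
  }, "")
  applicable <- scores != "NOT_APPLICABLE"
  out <- do.call(rbind, lapply(split(seq_len(nrow(responses)),
                                     responses$clinician_id), function(idx) {
    idx <- idx[applicable[idx]]
    data.frame(
      clinician_id = responses$clinician_id[[idx[1L]]],
      group = responses$group[[idx[1L]]],
      gender = if ("gender" %in% names(responses))
        responses$gender[[idx[1L]]] else NA_character_,
      n_correct = sum(scores[idx] == "CONCORDANT"),
      n_scenarios = length(idx), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$low_scorer <- out$n_correct / out$n_scenarios <= 0.5
  out
}

#' Low-scorer summary with an exact group comparison
#'
#' Builds the r x 2 table of (low scorers, others) by group, the overall
#' low-scorer proportion, and an exact p-value: the one-sided min-tail
#' Fisher test for two groups, the Freeman-Halton test otherwise. Accepts
#' either per-clinician scorecards (from [build_scorecards()] or a
#' fixture) or pre-aggregated group counts with columns `group`, `low`,
#' `total`.
#'
#' @param x Scorecard data frame (columns `group`/`gender`, `low_scorer`)
#'   or counts data frame (columns `group`, `low`, `total`).
#' @param grouping `"CLINICIAN_TYPE"` (the `group` column) or `"GENDER"`.
#' @return A list: `table` (a [contingency_table()]), `n_low`, `n_total`,
#'   `proportion`, `percent` (rounded half-up), `p_value`, `method`.
#' @export
low_scorer_summary <- function(x, grouping = c("CLINICIAN_TYPE", "GENDER")) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(x), nrow(x) > 0L)
  if (all(c("low", "total") %in% names(x))) {
    counts <- data.frame(group = x$group, low = x$low,
                         high = x$total - x$low)
  } else {
    g <- if (grouping == "GENDER") x$gender else x$group
    counts <- do.call(rbind, lapply(split(x$low_scorer, g), function(v)
      data.frame(low = sum(v), high = sum(!v))))
    counts <- data.frame(group = rownames(counts), counts,
                         row.names = NULL)
  }
  tab <- contingency_table(counts)
  p <- if (nrow(tab) == 2L) fisher_2x2(tab, "ONE_SIDED_MIN_TAIL")
  else freeman_halton(tab)
  n_low <- sum(tab[, 1L])
  n_total <- sum(tab)
  list(table = tab, n_low = n_low, n_total = n_total,
       proportion = n_low / n_total,
       percent = round_half_up(100 * n_low / n_total),
       p_value = p,
       method = if (nrow(tab) == 2L) "fisher_one_sided_min_tail"
       else "freeman_halton")
}

#' Pilot-study audit summary
#'
#' Summarizes stated agreement between endoscopist and tool over the pilot
#' records: agreement among all records, agreement excluding "issue"
#' records (incorrect tool use detected on chart review, age-driven
#' no-follow-up calls, and cases outside the tool's scope), the issue rate,
#' and discordance among the no-issue records. Percentages are rounded
#' half-up; the underlying fractions are returned alongside.
#'
#' @param records Data frame as returned by [table3_fixture()]: columns
#'   `endoscopist_id`, `stated_agreement`, `chart_review_agreement`,
#'   `exclusion`, `direction`, `would_change`.
#' @return A list of counts, proportions, and display percentages.
#' @export
pilot_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  n <- nrow(records)
  chart_mismatch <- records$stated_agreement &
    !is.na(records$chart_review_agreement) &
    !records$chart_review_agreement
  issue <- records$exclusion != "NONE" | chart_mismatch
  agree <- records$stated_agreement & !issue
  no_issue <- !issue
  n_agree <- sum(agree)
  n_no_issue <- sum(no_issue)
  n_discordant <- sum(no_issue & !records$stated_agreement)
  excl_counts <- table(factor(records$exclusion,
                              levels = c("NONE", "INCORRECT_TOOL_USE",
                                         "AGE_NO_FOLLOWUP",
                                         "NOT_APPLICABLE_OTHER")))
  pct <- function(num, den) round_half_up(100 * num / den)
  list(
    n = n,
    n_agree = n_agree,
    n_no_issue = n_no_issue,
    n_discordant_no_issue = n_discordant,
    n_issues = sum(issue),
    exclusion_counts = excl_counts,
    agreement_all = n_agree / n,
    agreement_all_pct = pct(n_agree, n),
    agreement_no_issue = n_agree / n_no_issue,
    agreement_no_issue_pct = pct(n_agree, n_no_issue),
    discordance_no_issue = n_discordant / n_no_issue,
    discordance_no_issue_pct = pct(n_discordant, n_no_issue),
    issue_rate = sum(issue) / n,
    issue_rate_pct = pct(sum(issue), n))
}

#' Direction of discordant recommendations
#'
#' Proportions of shorter- versus longer-than-recommended answers among
#' discordant items carrying a direction label.
#'
#' @param directions Character vector with values `"SHORTER"`, `"LONGER"`,
#'   or `NA` (no direction).
#' @return A list with counts, proportions, and rounded percentages; empty
#'   (n = 0) when nothing is discordant.
#' @export
direction_breakdown <- function(directions) {
  d <- directions[!is.na(directions)]
  d <- d[d %in% c("SHORTER", "LONGER")]
  if (!length(d))
    return(list(n = 0L, n_shorter = 0L, n_longer = 0L,
                shorter = NA_real_, longer = NA_real_,
                shorter_pct = NA_real_, longer_pct = NA_real_))
  n_s <- sum(d == "SHORTER")
  n_l <- sum(d == "LONGER")
  list(n = length(d), n_shorter = n_s, n_longer = n_l,
       shorter = n_s / length(d), longer = n_l / length(d),
       shorter_pct = round_half_up(100 * n_s / length(d)),
       longer_pct = round_half_up(100 * n_l / length(d)))
}
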