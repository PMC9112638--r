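# Deterministic mapping from patient + findings to a surveillance interval.
# Rules are evaluated independently; when several match, the elementwise
# minimum of the interval bounds wins ("most conservative" combination).

# Derived features the rule predicates are written over. Aggregation follows
# guideline count categories: adenoma counts pool tubular, tubulovillous/
# villous and HGD groups; serrated counts pool SSP with and without
# dysplasia. Unknown locations are treated as proximal (conservative).
findings_features <- function(f) {
  g <- f$polyp_groups
  hist <- vapply(g, function(x) x$histology, "")
  size <- vapply(g, function(x) x$max_size_mm, 0L)
  cnt  <- vapply(g, function(x) x$count, 0L)
  loc  <- vapply(g, function(x) x$location, "")
  res  <- vapply(g, function(x) x$resection, "")
  aden <- hist %in% ADENOMA_HISTOLOGIES
  serr <- hist %in% SERRATED_HISTOLOGIES
  hp   <- hist == "HYPERPLASTIC"
  mx <- function(v) if (length(v)) max(v) else 0L
  list(
    n_groups = length(g),
    adenoma_count = sum(cnt[aden]),
    adenoma_max_size = mx(size[aden]),
    serrated_count = sum(cnt[serr]),
    serrated_max_size = mx(size[serr]),
    villous_present = any(hist == "TUBULOVILLOUS_OR_VILLOUS"),
    hgd_present = any(hist == "ADENOMA_HGD"),
    ssp_dysplasia_present = any(hist == "SSP_DYSPLASIA"),
    tsa_present = any(hist == "TSA"),
    hp_max_size = mx(size[hp]),
    hp_rectosigmoid_max_size = mx(size[hp & loc == "RECTOSIGMOID"]),
    hp_proximal_max_size = mx(size[hp & loc != "RECTOSIGMOID"]),
    piecemeal_ge20 = any(res == "PIECEMEAL" & size >= 20))
}

rule_matches <- function(rule, feats) {
  for (feat in names(rule$when)) {
    v <- rule$when[[feat]]
    fv <- feats[[feat]]
    ok <- if (is.logical(v)) identical(fv, v) else (fv >= v[1] && fv <= v[2])
    if (!ok) return(FALSE)
  }
  TRUE
}

# ids of all matching index rules, in config order
match_index_rules <- function(ruleset, findings) {
  feats <- findings_features(findings)
  hit <- vapply(ruleset$index_rules, rule_matches, NA, feats = feats)
  names(ruleset$index_rules)[hit]
}

combine_rules <- function(ruleset, ids) {
  out <- NULL
  for (id in ids) {
    m <- ruleset$index_rules[[id]]$months
    out <- if (is.null(out)) m else interval_min(out, m)
  }
  out
}

#' Eligibility gate
#'
#' The tool covers the screening age group. Patients aged 75 or older,
#' patients with a hereditary colorectal cancer syndrome, and patients with
#' inflammatory bowel disease are out of its scope; screening decisions for
#' them are made case by case outside the tool.
#'
#' @param profile A [patient_profile()].
#' @return An `OUT_OF_SCOPE` recommendation when a gate fires, otherwise
#'   `NULL` (pass-through).
#' @examples
#' check_eligibility(patient_profile(80))
#' @export
check_eligibility <- function(profile) {
  stopifnot(inherits(profile, "patient_profile"))
  why <- character()
  if (profile$age_years >= 75) why <- c(why, "age >= 75")
  if (profile$hereditary_syndrome)
    why <- c(why, "hereditary CRC syndrome")
  if (profile$ibd) why <- c(why, "inflammatory bowel disease")
  if (length(why))
    return(new_recommendation("OUT_OF_SCOPE",
                              rationale = paste("out of scope:", why)))
  NULL
}

#' Collapse one examination into a risk class
#'
#' Summarizes a colonoscopy for the second-surveillance lookup: `NORMAL`
#' when no polyps were found; `HIGH_RISK` when any adenoma is 10 mm or
#' larger, any tubulovillous/villous or high-grade-dysplasia adenoma is
#' present, total adenoma count is 5 or more, any sessile serrated polyp is
#' 10 mm or larger or carries dysplasia, or a traditional serrated adenoma
#' is present; `LOW_RISK` otherwise.
#'
#' @param findings A [colonoscopy_findings()].
#' @return `"NORMAL"`, `"LOW_RISK"`, or `"HIGH_RISK"`.
#' @export
classify_risk <- function(findings) {
  stopifnot(inherits(findings, "colonoscopy_findings"))
  ft <- findings_features(findings)
  if (ft$n_groups == 0L) return("NORMAL")
  high <- ft$adenoma_max_size >= 10 || ft$hgd_present || ft$villous_present ||
    ft$adenoma_count >= 5 || ft$serrated_max_size >= 10 ||
    ft$ssp_dysplasia_present || ft$tsa_present
  if (high) "HIGH_RISK" else "LOW_RISK"
}

quality_gate <- function(findings) {
  if (!findings$cecum_reached || !findings$prep_adequate)
    return(new_recommendation(
      "CASE_BY_CASE",
      rationale = paste("repeat/complete high-quality examination:",
                        if (!findings$cecum_reached) "cecum not reached"
                        else "inadequate bowel preparation")))
  NULL
}

#' Recommendation after an index colonoscopy
#'
#' Evaluates every index rule of the rule set against the findings and
#' combines all matching intervals by elementwise minimum. A normal
#' examination yields the no-polyp interval (10 years under the default
#' rule set).
#'
#' @param profile A [patient_profile()] that has passed [check_eligibility()].
#' @param findings A [colonoscopy_findings()].
#' @param ruleset A [load_ruleset()] result (default: bundled rules).
#' @return A `recommendation`.
#' @examples
#' recommend_index(patient_profile(55), colonoscopy_findings())
#' @export
recommend_index <- function(profile, findings, ruleset = load_ruleset()) {
  stopifnot(inherits(findings, "colonoscopy_findings"))
  q <- quality_gate(findings)
  if (!is.null(q)) return(q)
  ids <- match_index_rules(ruleset, findings)
  if (!length(ids)) {
    ft <- findings_features(findings)
    fail("no index rule covers this findings signature: ",
         paste(names(ft), unlist(lapply(ft, format)), sep = "=",
               collapse = ", "))
  }
  iv <- combine_rules(ruleset, ids)
  new_recommendation("INTERVAL", iv, fired_rule_ids = ids,
                     rationale = paste0("index pathway: ", format_interval(iv),
                                        " (rules ", paste(ids, collapse = ", "),
                                        ")"))
}

#' Recommendation after a surveillance colonoscopy
#'
#' Looks up the second-surveillance cell keyed by the risk classes of the
#' prior and current examinations. When the current examination is not
#' normal, the result is the most conservative of that cell and the index
#' recommendation applied to the current findings.
#'
#' @inheritParams recommend_index
#' @param prior,current [colonoscopy_findings()] of the previous and the
#'   current examination.
#' @return A `recommendation`.
#' @export
recommend_surveillance <- function(profile, prior, current,
                                   ruleset = load_ruleset()) {
  stopifnot(inherits(prior, "colonoscopy_findings"),
            inherits(current, "colonoscopy_findings"))
  q <- quality_gate(current)
  if (!is.null(q)) return(q)
  rp <- classify_risk(prior)
  rc <- classify_risk(current)
  cell <- ruleset$surveillance_step[[rp]][[rc]]
  if (is.null(cell)) fail("surveillance step grid has no cell (", rp, ", ",
                          rc, ")")
  step_id <- paste0("step_", rp, "_", rc)
  ids <- step_id
  iv <- cell
  why <- paste0("surveillance pathway: prior ", rp, ", current ", rc,
                " -> ", format_interval(cell))
  if (rc != "NORMAL") {
    idx <- recommend_index(profile, current, ruleset)
    iv <- interval_min(iv, idx$interval)
    ids <- c(ids, idx$fired_rule_ids)
    why <- c(why, idx$rationale)
  }
  new_recommendation("INTERVAL", iv, fired_rule_ids = ids, rationale = why)
}

#' Recommendation after resection of colorectal cancer
#'
#' The post-resection sequence (from USMSTF, which covers the scenario CAG
#' does not): first clearing colonoscopy at 12 months, next at 36 months,
#' then every 60 months. Polyp findings tighten the interval through the
#' most-conservative combination with the index rules.
#'
#' @inheritParams recommend_index
#' @return A `recommendation`.
#' @export
recommend_post_crc <- function(profile, findings, ruleset = load_ruleset()) {
  stopifnot(inherits(profile, "patient_profile"))
  if (!profile$crc_history)
    fail("recommend_post_crc requires a profile with crc_history set")
  q <- quality_gate(findings)
  if (!is.null(q)) return(q)
  k <- profile$post_resection_colonoscopy_count
  key <- if (k >= 2L) "2plus" else as.character(k)
  iv <- ruleset$post_crc_sequence[[key]]
  ids <- paste0("post_crc_", key)
  why <- paste0("post-CRC pathway: ", k, " prior post-resection ",
                "colonoscopies -> ", format_interval(iv))
  if (length(findings$polyp_groups)) {
    idx <- recommend_index(profile, findings, ruleset)
    iv <- interval_min(iv, idx$interval)
    ids <- c(ids, idx$fired_rule_ids)
    why <- c(why, idx$rationale)
  }
  new_recommendation("INTERVAL", iv, fired_rule_ids = ids, rationale = why)
}

#' Family-history modifier
#'
#' High-risk family history (two or more first-degree relatives with CRC,
#' any diagnosed before 60, or an advanced adenoma in a relative diagnosed
#' before 60) caps the interval at the rule set's high-risk cap (60 months
#' by default); a single affected relative diagnosed at 60 or later caps at
#' the low-risk cap (120 months). Caps are elementwise minima, so they never
#' lengthen a recommendation, and the operation is idempotent.
#'
#' @param base An `INTERVAL` recommendation.
#' @param fh A [family_history()].
#' @param age_years Patient age (kept for signature symmetry with the
#'   dispatcher; the default caps do not vary by age).
#' @param ruleset A [load_ruleset()] result.
#' @return A `recommendation`.
#' @export
apply_family_history <- function(base, fh, age_years = NA_integer_,
                                 ruleset = load_ruleset()) {
  stopifnot(inherits(base, "recommendation"),
            inherits(fh, "family_history"))
  if (base$status != "INTERVAL")
    fail("apply_family_history requires an INTERVAL recommendation")
  high <- fh$fdr_crc_count >= 2L ||
    (!is.na(fh$youngest_dx_age) && fh$youngest_dx_age < 60 &&
       (fh$fdr_crc_count >= 1L || fh$fdr_advanced_adenoma))
  low <- !high && (fh$fdr_crc_count >= 1L || fh$fdr_advanced_adenoma)
  cap <- if (high) ruleset$family_history_rules$high_risk_cap_months
  else if (low) ruleset$family_history_rules$low_risk_cap_months
  else return(base)
  capped <- interval_min(base$interval, interval_range(cap, cap))
  if (capped$min_months == base$interval$min_months &&
      capped$max_months == base$interval$max_months) return(base)
  rule_id <- if (high) "fh_high_risk_cap" else "fh_low_risk_cap"
  new_recommendation("INTERVAL", capped,
                     fired_rule_ids = c(base$fired_rule_ids, rule_id),
                     rationale = c(base$rationale,
                                   paste0("family history caps interval at ",
                                          cap, " months")))
}

#' Recommend a surveillance interval
#'
#' The dispatcher: the eligibility gate runs first, then the examination
#' quality gate; a personal history of CRC routes to the post-resection
#' pathway, a prior examination to the surveillance pathway, and anything
#' else to the index pathway. The family-history cap is applied last.
#'
#' @param profile A [patient_profile()].
#' @param current [colonoscopy_findings()] of the current examination.
#' @param prior [colonoscopy_findings()] of the previous examination, or
#'   `NULL` when this is the patient's first colonoscopy.
#' @param ruleset A [load_ruleset()] result.
#' @return A `recommendation`: an interval in months, or an
#'   `OUT_OF_SCOPE` / `CASE_BY_CASE` status.
#' @examples
#' recommend(patient_profile(55), colonoscopy_findings())
#' recommend(patient_profile(80), colonoscopy_findings())
#' @export
recommend <- function(profile, current, prior = NULL,
                      ruleset = load_ruleset()) {
  gate <- check_eligibility(profile)
  if (!is.null(gate)) return(gate)
  rec <- if (profile$crc_history)
    recommend_post_crc(profile, current, ruleset)
  else if (!is.null(prior))
    recommend_surveillance(profile, prior, current, ruleset)
  else recommend_index(profile, current, ruleset)
  if (rec$status == "INTERVAL")
    rec <- apply_family_history(rec, profile$family_history,
                                profile$age_years, ruleset)
  rec
}
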