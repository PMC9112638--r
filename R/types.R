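#' @keywords internal
"_PACKAGE"

HISTOLOGIES <- c("TUBULAR_ADENOMA", "TUBULOVILLOUS_OR_VILLOUS", "ADENOMA_HGD",
                 "SSP", "SSP_DYSPLASIA", "TSA", "HYPERPLASTIC")
LOCATIONS   <- c("RECTOSIGMOID", "PROXIMAL", "UNKNOWN")
RESECTIONS  <- c("COMPLETE_ENBLOC", "PIECEMEAL", "INCOMPLETE")
ADENOMA_HISTOLOGIES  <- c("TUBULAR_ADENOMA", "TUBULOVILLOUS_OR_VILLOUS", "ADENOMA_HGD")
SERRATED_HISTOLOGIES <- c("SSP", "SSP_DYSPLASIA")
RISK_CLASSES <- c("NORMAL", "LOW_RISK", "HIGH_RISK")
REC_STATUSES <- c("INTERVAL", "NO_FURTHER", "CASE_BY_CASE", "OUT_OF_SCOPE")

fail <- function(..., field = NULL) {
  msg <- paste0(...)
  if (!is.null(field)) msg <- paste0(msg, " [field: ", field, "]")
  stop(msg, call. = FALSE)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

#' One histology group of polyps found at colonoscopy
#'
#' A `polyp_group` records all polyps of one histology at one location:
#' how many, the largest diameter, and how the largest lesion was resected.
#'
#' @param histology One of `"TUBULAR_ADENOMA"`, `"TUBULOVILLOUS_OR_VILLOUS"`,
#'   `"ADENOMA_HGD"`, `"SSP"`, `"SSP_DYSPLASIA"`, `"TSA"`, `"HYPERPLASTIC"`.
#' @param count Number of polyps in the group (integer, at least 1).
#' @param max_size_mm Largest diameter in millimetres (integer, at least 1).
#' @param location `"RECTOSIGMOID"`, `"PROXIMAL"`, or `"UNKNOWN"`. Unknown
#'   locations are treated as proximal (the conservative reading) by the
#'   rule engine.
#' @param resection `"COMPLETE_ENBLOC"` (default), `"PIECEMEAL"`, or
#'   `"INCOMPLETE"`.
#' @return An object of class `polyp_group`.
#' @examples
#' polyp_group("TUBULAR_ADENOMA", count = 2, max_size_mm = 5)
#' @export
polyp_group <- function(histology, count = 1L, max_size_mm = 5L,
                        location = "PROXIMAL", resection = "COMPLETE_ENBLOC") {
  if (!is.character(histology) || length(histology) != 1L ||
      !histology %in% HISTOLOGIES)
    fail("histology must be one of ", paste(HISTOLOGIES, collapse = ", "),
         field = "histology")
  if (!is_count1(count) || count < 1) fail("count must be an integer >= 1",
                                           field = "count")
  if (!is_count1(max_size_mm) || max_size_mm < 1)
    fail("max_size_mm must be an integer >= 1", field = "max_size_mm")
  if (!location %in% LOCATIONS) fail("unknown location '", location, "'",
                                     field = "location")
  if (!resection %in% RESECTIONS) fail("unknown resection '", resection, "'",
                                       field = "resection")
  structure(list(histology = histology, count = as.integer(count),
                 max_size_mm = as.integer(max_size_mm), location = location,
                 resection = resection),
            class = "polyp_group")
}

#' Findings of a single colonoscopy
#'
#' Wraps zero or more [polyp_group()]s together with the procedure-quality
#' flags. An empty group list is a normal examination. Groups sharing a
#' (histology, location) pair are merged: counts add, the larger size and
#' the less favourable resection mode win.
#'
#' @param polyp_groups List of [polyp_group()] objects; empty list for a
#'   normal colonoscopy.
#' @param cecum_reached Was the cecum intubated? Incomplete examinations are
#'   routed to a case-by-case recommendation, not an interval.
#' @param prep_adequate Was bowel preparation adequate?
#' @param ordinal `"INDEX"` for a first (screening) examination,
#'   `"SURVEILLANCE"` for a follow-up.
#' @return An object of class `colonoscopy_findings`.
#' @examples
#' colonoscopy_findings(list(polyp_group("SSP", 1, 6)))
#' colonoscopy_findings() # normal exam
#' @export
colonoscopy_findings <- function(polyp_groups = list(), cecum_reached = TRUE,
                                 prep_adequate = TRUE, ordinal = "INDEX") {
  if (!is.list(polyp_groups)) fail("polyp_groups must be a list",
                                   field = "polyp_groups")
  for (g in polyp_groups)
    if (!inherits(g, "polyp_group"))
      fail("every element of polyp_groups must be a polyp_group",
           field = "polyp_groups")
  if (!is_flag(cecum_reached)) fail("cecum_reached must be TRUE/FALSE",
                                    field = "cecum_reached")
  if (!is_flag(prep_adequate)) fail("prep_adequate must be TRUE/FALSE",
                                    field = "prep_adequate")
  if (!ordinal %in% c("INDEX", "SURVEILLANCE"))
    fail("ordinal must be INDEX or SURVEILLANCE", field = "ordinal")
  out <- structure(list(polyp_groups = polyp_groups,
                        cecum_reached = cecum_reached,
                        prep_adequate = prep_adequate, ordinal = ordinal),
                   class = "colonoscopy_findings")
  normalize_findings(out)
}

# Merge groups that share (histology, location): counts add, max size and the
# worst resection mode win. Guarantees at most one group per pair.
normalize_findings <- function(f) {
  g <- f$polyp_groups
  if (length(g) < 2L) return(f)
  keys <- vapply(g, function(x) paste(x$histology, x$location, sep = "|"), "")
  if (!anyDuplicated(keys)) return(f)
  res_rank <- c(COMPLETE_ENBLOC = 1L, PIECEMEAL = 2L, INCOMPLETE = 3L)
  merged <- lapply(unique(keys), function(k) {
    gs <- g[keys == k]
    polyp_group(histology = gs[[1L]]$histology,
                count = sum(vapply(gs, function(x) x$count, 0L)),
                max_size_mm = max(vapply(gs, function(x) x$max_size_mm, 0L)),
                location = gs[[1L]]$location,
                resection = names(which.max(
                  res_rank[vapply(gs, function(x) x$resection, "")])))
  })
  f$polyp_groups <- merged
  f
}

#' Family history of colorectal cancer and advanced adenoma
#'
#' @param fdr_crc_count Number of first-degree relatives with colorectal
#'   cancer (integer, 0 or more).
#' @param youngest_dx_age Age at diagnosis of the youngest affected relative;
#'   required when any relative is affected, `NA` otherwise.
#' @param fdr_advanced_adenoma Any first-degree relative with a documented
#'   advanced adenoma?
#' @return An object of class `family_history`.
#' @export
family_history <- function(fdr_crc_count = 0L, youngest_dx_age = NA,
                           fdr_advanced_adenoma = FALSE) {
  if (!is_count1(fdr_crc_count) || fdr_crc_count < 0)
    fail("fdr_crc_count must be an integer >= 0", field = "fdr_crc_count")
  if (!is_flag(fdr_advanced_adenoma))
    fail("fdr_advanced_adenoma must be TRUE/FALSE",
         field = "fdr_advanced_adenoma")
  affected <- fdr_crc_count >= 1L || fdr_advanced_adenoma
  if (affected) {
    if (is.na(youngest_dx_age) || !is_count1(youngest_dx_age))
      fail("youngest_dx_age is required when a first-degree relative is ",
           "affected", field = "youngest_dx_age")
  } else if (!is.na(youngest_dx_age)) {
    fail("youngest_dx_age must be absent when no relative is affected",
         field = "youngest_dx_age")
  }
  structure(list(fdr_crc_count = as.integer(fdr_crc_count),
                 youngest_dx_age = if (affected) as.integer(youngest_dx_age) else NA_integer_,
                 fdr_advanced_adenoma = fdr_advanced_adenoma),
            class = "family_history")
}

#' Patient profile driving pathway dispatch
#'
#' @param age_years Age in completed years. The tool covers the screening age
#'   group; patients aged 75 or older are out of scope.
#' @param crc_history Personal history of resected colorectal cancer?
#' @param months_since_crc_resection Months since the resection; required iff
#'   `crc_history` is set.
#' @param post_resection_colonoscopy_count Completed post-resection
#'   colonoscopies (0 means this is the first clearing examination).
#' @param family_history A [family_history()] object.
#' @param hereditary_syndrome Known hereditary colorectal cancer syndrome
#'   (out of scope)?
#' @param ibd Inflammatory bowel disease (out of scope)?
#' @return An object of class `patient_profile`.
#' @examples
#' patient_profile(age_years = 55)
#' @export
patient_profile <- function(age_years, crc_history = FALSE,
                            months_since_crc_resection = NA,
                            post_resection_colonoscopy_count = 0L,
                            family_history = polypsurv::family_history(),
                            hereditary_syndrome = FALSE, ibd = FALSE) {
  if (!is_count1(age_years) || age_years < 18 || age_years > 120)
    fail("age_years must be an integer in [18, 120]", field = "age_years")
  if (!is_flag(crc_history)) fail("crc_history must be TRUE/FALSE",
                                  field = "crc_history")
  if (crc_history) {
    if (is.na(months_since_crc_resection) ||
        !is_count1(months_since_crc_resection) ||
        months_since_crc_resection < 0)
      fail("months_since_crc_resection is required (integer >= 0) when ",
           "crc_history is set", field = "months_since_crc_resection")
  } else if (!is.na(months_since_crc_resection)) {
    fail("months_since_crc_resection must be absent without crc_history",
         field = "months_since_crc_resection")
  }
  if (!is_count1(post_resection_colonoscopy_count) ||
      post_resection_colonoscopy_count < 0)
    fail("post_resection_colonoscopy_count must be an integer >= 0",
         field = "post_resection_colonoscopy_count")
  if (!inherits(family_history, "family_history"))
    fail("family_history must be a family_history object",
         field = "family_history")
  if (!is_flag(hereditary_syndrome))
    fail("hereditary_syndrome must be TRUE/FALSE",
         field = "hereditary_syndrome")
  if (!is_flag(ibd)) fail("ibd must be TRUE/FALSE", field = "ibd")
  structure(list(
    age_years = as.integer(age_years), crc_history = crc_history,
    months_since_crc_resection =
      if (crc_history) as.integer(months_since_crc_resection) else NA_integer_,
    post_resection_colonoscopy_count =
      as.integer(post_resection_colonoscopy_count),
    family_history = family_history,
    hereditary_syndrome = hereditary_syndrome, ibd = ibd),
    class = "patient_profile")
}

#' A surveillance interval, in months
#'
#' Intervals are stored in months so that a 6-month post-piecemeal check and
#' a 5-10 year range live on the same scale; [format_interval()] renders
#' years for display.
#'
#' @param min_months,max_months Positive integers with
#'   `min_months <= max_months`.
#' @return An object of class `interval_range`.
#' @export
interval_range <- function(min_months, max_months = min_months) {
  if (!is_count1(min_months) || !is_count1(max_months) ||
      min_months <= 0 || max_months < min_months)
    fail("interval bounds must satisfy 0 < min_months <= max_months",
         field = "interval")
  structure(list(min_months = as.integer(min_months),
                 max_months = as.integer(max_months)),
            class = "interval_range")
}

#' @rdname interval_range
#' @param x An `interval_range`.
#' @export
format_interval <- function(x) {
  stopifnot(inherits(x, "interval_range"))
  fmt1 <- function(m) {
    if (m %% 12 == 0) paste0(m / 12, " y") else paste0(m, " mo")
  }
  if (x$min_months == x$max_months) fmt1(x$min_months)
  else if (x$min_months %% 12 == 0 && x$max_months %% 12 == 0)
    paste0(x$min_months / 12, "-", x$max_months / 12, " y")
  else paste0(x$min_months, "-", x$max_months, " mo")
}

# elementwise minimum: the most conservative combination of two intervals
interval_min <- function(a, b) {
  interval_range(min(a$min_months, b$min_months),
                 min(a$max_months, b$max_months))
}

new_recommendation <- function(status, interval = NULL,
                               fired_rule_ids = character(),
                               rationale = character()) {
  if (!status %in% REC_STATUSES) fail("unknown recommendation status")
  if (status == "INTERVAL") {
    if (is.null(interval) || !inherits(interval, "interval_range"))
      fail("an INTERVAL recommendation requires an interval_range")
    if (length(fired_rule_ids) == 0L)
      fail("an INTERVAL recommendation must cite at least one rule")
  } else if (!is.null(interval)) {
    fail("only INTERVAL recommendations carry an interval")
  }
  structure(list(status = status, interval = interval,
                 fired_rule_ids = fired_rule_ids, rationale = rationale),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat("<recommendation> ", x$status, sep = "")
  if (x$status == "INTERVAL")
    cat(": repeat in ", format_interval(x$interval),
        " [", x$interval$min_months, ", ", x$interval$max_months, "] months",
        sep = "")
  cat("\n")
  if (length(x$fired_rule_ids))
    cat("  rules: ", paste(x$fired_rule_ids, collapse = ", "), "\n", sep = "")
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' @export
print.polyp_group <- function(x, ...) {
  cat("<polyp_group> ", x$count, "x ", x$histology, ", ", x$max_size_mm,
      " mm, ", x$location, ", ", x$resection, "\n", sep = "")
  invisible(x)
}

#' @export
print.colonoscopy_findings <- function(x, ...) {
  cat("<colonoscopy_findings> ", x$ordinal, ", ",
      length(x$polyp_groups), " polyp group(s)",
      if (!x$cecum_reached) ", cecum NOT reached",
      if (!x$prep_adequate) ", inadequate prep", "\n", sep = "")
  for (g in x$polyp_groups) print(g)
  invisible(x)
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile> age ", x$age_years,
      if (x$crc_history) paste0(", CRC resected ", x$months_since_crc_resection,
                                " mo ago (", x$post_resection_colonoscopy_count,
                                " post-resection scopes)"),
      if (x$hereditary_syndrome) ", hereditary syndrome",
      if (x$ibd) ", IBD", "\n", sep = "")
  invisible(x)
}
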