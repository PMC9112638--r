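# Readers and writers for case records and recommendations. JSON is the
# canonical, fully faithful format (nested groups, any number of locations
# per histology). The flat CSV dialect carries one row per case with
# per-histology count/size/location/resection columns, so it can hold at
# most one group per histology; the writer refuses cases outside that
# subset rather than drop information. UTF-8, comma-separated, header row
# required; missing values are empty strings.

profile_to_list <- function(p) {
  list(age_years = p$age_years, crc_history = p$crc_history,
       months_since_crc_resection = p$months_since_crc_resection,
       post_resection_colonoscopy_count = p$post_resection_colonoscopy_count,
       family_history = list(
         fdr_crc_count = p$family_history$fdr_crc_count,
         youngest_dx_age = p$family_history$youngest_dx_age,
         fdr_advanced_adenoma = p$family_history$fdr_advanced_adenoma),
       hereditary_syndrome = p$hereditary_syndrome, ibd = p$ibd)
}

findings_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  list(polyp_groups = lapply(f$polyp_groups, unclass),
       cecum_reached = f$cecum_reached, prep_adequate = f$prep_adequate,
       ordinal = f$ordinal)
}

list_to_profile <- function(x) {
  fh <- x$family_history %||% list()
  patient_profile(
    age_years = x$age_years,
    crc_history = isTRUE(x$crc_history),
    months_since_crc_resection = x$months_since_crc_resection %||% NA,
    post_resection_colonoscopy_count =
      x$post_resection_colonoscopy_count %||% 0L,
    family_history = family_history(
      fh$fdr_crc_count %||% 0L, fh$youngest_dx_age %||% NA,
      isTRUE(fh$fdr_advanced_adenoma)),
    hereditary_syndrome = isTRUE(x$hereditary_syndrome),
    ibd = isTRUE(x$ibd))
}

list_to_findings <- function(x) {
  if (is.null(x)) return(NULL)
  colonoscopy_findings(
    polyp_groups = lapply(x$polyp_groups %||% list(), function(g)
      polyp_group(g$histology, g$count %||% 1L, g$max_size_mm %||% 5L,
                  g$location %||% "PROXIMAL",
                  g$resection %||% "COMPLETE_ENBLOC")),
    cecum_reached = x$cecum_reached %||% TRUE,
    prep_adequate = x$prep_adequate %||% TRUE,
    ordinal = x$ordinal %||% "INDEX")
}

#' Read and write case records
#'
#' `write_cases_json()` / `read_cases_json()` round-trip any list of case
#' records (as produced by [generate_cohort()]) exactly.
#' `write_cases_csv()` / `read_cases_csv()` use the flat one-row-per-case
#' dialect described in the package documentation.
#'
#' @param cases List of records (`profile`, `prior`, `current`).
#' @param path File path.
#' @return `read_*` return the list of records; `write_*` return `path`
#'   invisibly.
#' @export
write_cases_json <- function(cases, path) {
  payload <- lapply(cases, function(r)
    list(profile = profile_to_list(r$profile),
         prior = findings_to_list(r$prior),
         current = findings_to_list(r$current)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cases_json
#' @export
read_cases_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    rec <- tryCatch(
      list(profile = list_to_profile(r$profile),
           prior = list_to_findings(r$prior),
           current = list_to_findings(r$current)),
      error = function(e) fail("record ", i, ": ", conditionMessage(e)))
    rec
  })
}

HIST_ABBR <- c(TUBULAR_ADENOMA = "ta", TUBULOVILLOUS_OR_VILLOUS = "tv",
               ADENOMA_HGD = "hgd", SSP = "ssp", SSP_DYSPLASIA = "sspd",
               TSA = "tsa", HYPERPLASTIC = "hp")

findings_to_row <- function(f, prefix) {
  row <- list()
  row[[paste0(prefix, "_present")]] <- !is.null(f)
  if (is.null(f)) f <- colonoscopy_findings()
  row[[paste0(prefix, "_cecum_reached")]] <- f$cecum_reached
  row[[paste0(prefix, "_prep_adequate")]] <- f$prep_adequate
  hists <- vapply(f$polyp_groups, function(g) g$histology, "")
  if (anyDuplicated(hists))
    fail("CSV cannot represent two groups of one histology at different ",
         "locations; use JSON")
  for (h in names(HIST_ABBR)) {
    a <- HIST_ABBR[[h]]
    g <- f$polyp_groups[hists == h]
    row[[paste0(prefix, "_", a, "_count")]] <-
      if (length(g)) g[[1]]$count else NA_integer_
    row[[paste0(prefix, "_", a, "_size")]] <-
      if (length(g)) g[[1]]$max_size_mm else NA_integer_
    row[[paste0(prefix, "_", a, "_location")]] <-
      if (length(g)) g[[1]]$location else NA_character_
    row[[paste0(prefix, "_", a, "_resection")]] <-
      if (length(g)) g[[1]]$resection else NA_character_
  }
  row
}

row_to_findings <- function(row, prefix, ordinal) {
  if (!isTRUE(row[[paste0(prefix, "_present")]])) return(NULL)
  groups <- list()
  for (h in names(HIST_ABBR)) {
    a <- HIST_ABBR[[h]]
    cnt <- row[[paste0(prefix, "_", a, "_count")]]
    if (!is.na(cnt))
      groups <- c(groups, list(polyp_group(
        h, cnt, row[[paste0(prefix, "_", a, "_size")]],
        row[[paste0(prefix, "_", a, "_location")]],
        row[[paste0(prefix, "_", a, "_resection")]])))
  }
  colonoscopy_findings(groups,
                       cecum_reached =
                         isTRUE(row[[paste0(prefix, "_cecum_reached")]]),
                       prep_adequate =
                         isTRUE(row[[paste0(prefix, "_prep_adequate")]]),
                       ordinal = ordinal)
}

#' @rdname write_cases_json
#' @export
write_cases_csv <- function(cases, path) {
  rows <- lapply(cases, function(r) {
    p <- r$profile
    c(list(age_years = p$age_years, crc_history = p$crc_history,
           months_since_crc_resection = p$months_since_crc_resection,
           post_resection_colonoscopy_count =
             p$post_resection_colonoscopy_count,
           fdr_crc_count = p$family_history$fdr_crc_count,
           youngest_dx_age = p$family_history$youngest_dx_age,
           fdr_advanced_adenoma = p$family_history$fdr_advanced_adenoma,
           hereditary_syndrome = p$hereditary_syndrome, ibd = p$ibd),
      findings_to_row(r$current, "cur"), findings_to_row(r$prior, "prior"))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cases_json
#' @export
read_cases_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    row <- lapply(row, function(v) if (is.character(v) && !is.na(v) &&
                                         v == "") NA else v)
    tryCatch({
      prior <- row_to_findings(row, "prior", "INDEX")
      list(profile = patient_profile(
        age_years = row$age_years,
        crc_history = isTRUE(row$crc_history),
        months_since_crc_resection = row$months_since_crc_resection,
        post_resection_colonoscopy_count =
          row$post_resection_colonoscopy_count,
        family_history = family_history(
          row$fdr_crc_count, row$youngest_dx_age,
          isTRUE(row$fdr_advanced_adenoma)),
        hereditary_syndrome = isTRUE(row$hereditary_syndrome),
        ibd = isTRUE(row$ibd)),
        prior = prior,
        current = row_to_findings(row, "cur",
                                  if (is.null(prior)) "INDEX"
                                  else "SURVEILLANCE"))
    }, error = function(e) fail("row ", i, ": ", conditionMessage(e)))
  })
}

recommendation_to_list <- function(rec) {
  list(status = rec$status,
       min_months = if (!is.null(rec$interval)) rec$interval$min_months,
       max_months = if (!is.null(rec$interval)) rec$interval$max_months,
       display = if (!is.null(rec$interval)) format_interval(rec$interval),
       fired_rule_ids = rec$fired_rule_ids, rationale = rec$rationale)
}

#' Batch recommendations for a list of cases
#'
#' @param cases List of case records.
#' @param ruleset A [load_ruleset()] result.
#' @return A list of `recommendation` objects, one per case.
#' @export
recommend_cases <- function(cases, ruleset = load_ruleset()) {
  lapply(seq_along(cases), function(i) {
    r <- cases[[i]]
    tryCatch(recommend(r$profile, r$current, r$prior, ruleset),
             error = function(e) fail("record ", i, ": ",
                                      conditionMessage(e)))
  })
}
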