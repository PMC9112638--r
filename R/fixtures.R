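# Seeded synthetic cohorts spanning the rule space, and constant fixtures
# encoding the published audit tables. The published tables carry only
# group-level counts (raw per-clinician answers are unpublished), so the
# scorecard-level detail behind them is synthetic, generated to match the
# printed margins.

#' Specification of a synthetic cohort
#'
#' Mixture weights emulate a screening-age colonoscopy population with
#' mixed polyp findings spanning every rule category; they are test
#' scaffolding, not an epidemiological model. Each weight block must sum
#' to 1.
#'
#' @param n Number of records.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param pathway_weights Probabilities of index / surveillance / post-CRC
#'   records.
#' @param p_normal Probability that an examination finds no polyps.
#' @param histology_weights Per-group histology probabilities (named after
#'   the seven categories).
#' @param count_band_weights Probabilities of the 1-2 / 3-4 / 5-10 / >10
#'   count bands.
#' @param size_band_weights Probabilities of the <10 / 10-19 / >=20 mm
#'   size bands.
#' @param location_weights Rectosigmoid / proximal / unknown.
#' @param resection_weights Complete en-bloc / piecemeal / incomplete.
#' @param exclusion_rate Probability that a record is out of scope (split
#'   evenly between age >= 75, hereditary syndrome, and IBD).
#' @param fh_weights None / single relative diagnosed at 60+ / relative
#'   diagnosed before 60 / two or more relatives / advanced adenoma in a
#'   relative.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 500L, seed = 1L,
                        pathway_weights = c(INDEX = 0.5, SURVEILLANCE = 0.3,
                                            POST_CRC = 0.2),
                        p_normal = 0.25,
                        histology_weights = c(
                          TUBULAR_ADENOMA = 0.35,
                          TUBULOVILLOUS_OR_VILLOUS = 0.10,
                          ADENOMA_HGD = 0.07, SSP = 0.20,
                          SSP_DYSPLASIA = 0.08, TSA = 0.05,
                          HYPERPLASTIC = 0.15),
                        count_band_weights = c(0.55, 0.20, 0.15, 0.10),
                        size_band_weights = c(0.60, 0.25, 0.15),
                        location_weights = c(RECTOSIGMOID = 0.3,
                                             PROXIMAL = 0.6, UNKNOWN = 0.1),
                        resection_weights = c(COMPLETE_ENBLOC = 0.75,
                                              PIECEMEAL = 0.20,
                                              INCOMPLETE = 0.05),
                        exclusion_rate = 0.09,
                        fh_weights = c(none = 0.70, fdr_ge60 = 0.10,
                                       fdr_lt60 = 0.10, fdr_multi = 0.05,
                                       fdr_adenoma = 0.05)) {
  if (!is_count1(n) || n < 1) fail("n must be an integer >= 1")
  if (!is_count1(seed)) fail("seed must be an integer")
  blocks <- list(pathway_weights = pathway_weights,
                 histology_weights = histology_weights,
                 count_band_weights = count_band_weights,
                 size_band_weights = size_band_weights,
                 location_weights = location_weights,
                 resection_weights = resection_weights,
                 fh_weights = fh_weights)
  for (b in names(blocks)) {
    w <- blocks[[b]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      fail(b, " must be non-negative and sum to 1")
  }
  if (p_normal < 0 || p_normal > 1 || exclusion_rate < 0 ||
      exclusion_rate > 1)
    fail("p_normal and exclusion_rate must lie in [0, 1]")
  structure(c(list(n = as.integer(n), seed = as.integer(seed),
                   p_normal = p_normal, exclusion_rate = exclusion_rate),
              blocks),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Deterministic given `spec$seed`; every record passes type validation.
#' With the default weights and n of 500 or more, every bundled index rule
#' matches at least one record's findings.
#'
#' @param spec A [cohort_spec()].
#' @return A list of records, each a list with `profile`
#'   ([patient_profile()]), `prior` ([colonoscopy_findings()] or `NULL`),
#'   and `current`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 20, seed = 7))
#' recommend(cohort[[1]]$profile, cohort[[1]]$current, cohort[[1]]$prior)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  pick <- function(w) sample(names(w), 1L, prob = w)
  gen_group <- function() {
    band_c <- sample(4L, 1L, prob = spec$count_band_weights)
    count <- switch(band_c, sample(1:2, 1L), sample(3:4, 1L),
                    sample(5:10, 1L), sample(11:15, 1L))
    band_s <- sample(3L, 1L, prob = spec$size_band_weights)
    size <- switch(band_s, sample(1:9, 1L), sample(10:19, 1L),
                   sample(20:35, 1L))
    polyp_group(pick(spec$histology_weights), count, size,
                pick(spec$location_weights), pick(spec$resection_weights))
  }
  gen_findings <- function(ordinal) {
    if (stats::runif(1) < spec$p_normal)
      return(colonoscopy_findings(ordinal = ordinal))
    colonoscopy_findings(replicate(sample(1:3, 1L), gen_group(),
                                   simplify = FALSE), ordinal = ordinal)
  }
  gen_fh <- function() {
    switch(pick(spec$fh_weights),
           none = family_history(),
           fdr_ge60 = family_history(1L, sample(60:80, 1L)),
           fdr_lt60 = family_history(1L, sample(40:59, 1L)),
           fdr_multi = family_history(sample(2:3, 1L), sample(45:70, 1L)),
           fdr_adenoma = family_history(0L, sample(45:70, 1L),
                                        fdr_advanced_adenoma = TRUE))
  }

  lapply(seq_len(spec$n), function(i) {
    excluded <- stats::runif(1) < spec$exclusion_rate
    excl_kind <- if (excluded) sample(c("age", "hereditary", "ibd"), 1L)
    age <- if (identical(excl_kind, "age")) sample(75:90, 1L)
    else sample(50:74, 1L)
    pathway <- pick(spec$pathway_weights)
    crc <- pathway == "POST_CRC"
    profile <- patient_profile(
      age_years = age, crc_history = crc,
      months_since_crc_resection = if (crc) sample(3:60, 1L) else NA,
      post_resection_colonoscopy_count =
        if (crc) sample(0:3, 1L) else 0L,
      family_history = gen_fh(),
      hereditary_syndrome = identical(excl_kind, "hereditary"),
      ibd = identical(excl_kind, "ibd"))
    prior <- if (pathway == "SURVEILLANCE") gen_findings("INDEX")
    current <- gen_findings(if (pathway == "SURVEILLANCE") "SURVEILLANCE"
                            else "INDEX")
    list(profile = profile, prior = prior, current = current)
  })
}

#' Grouped scorecard fixture of the knowledge audit
#'
#' The printed group-level counts of the clinician-knowledge evaluation:
#' low scorers (at most 50 percent of scenarios concordant with
#' guidelines) by clinician type and by gender, for the 7-scenario battery
#' (19 clinicians; surgeons and surgery residents) and the 12-scenario
#' battery (10 clinicians). Because raw per-clinician answers were not
#' published, `scorecards_7` and `scorecards_12` are synthetic
#' per-clinician scorecards generated (seed 0) to reproduce the
#' clinician-type margins exactly; the printed gender margins of the
#' 7-scenario battery are internally inconsistent with its total row
#' (6/13 + 3/6 = 9, total 10/19) and are therefore kept only as the
#' printed count tables `gender_7` / `gender_12`.
#'
#' @return A list of data frames: `counts_7`, `counts_12`, `gender_7`,
#'   `gender_12`, `scorecards_7`, `scorecards_12`.
#' @export
table2_fixture <- function() {
  counts_7 <- data.frame(
    group = c("SURGEON", "GASTROENTEROLOGIST", "PCP", "RESIDENT"),
    low = c(2L, 2L, 3L, 3L), total = c(5L, 4L, 4L, 6L),
    stringsAsFactors = FALSE)
  counts_12 <- data.frame(
    group = c("GASTROENTEROLOGIST", "PCP", "RESIDENT"),
    low = c(2L, 2L, 1L), total = c(4L, 4L, 2L), stringsAsFactors = FALSE)
  gender_7 <- data.frame(group = c("MALE", "FEMALE"), low = c(6L, 3L),
                         total = c(13L, 6L), stringsAsFactors = FALSE)
  gender_12 <- data.frame(group = c("MALE", "FEMALE"), low = c(3L, 2L),
                          total = c(5L, 5L), stringsAsFactors = FALSE)
  mk_cards <- function(counts, n_scen) {
    low_score <- as.integer(floor(n_scen / 2))      # 3/7, 6/12
    high_score <- as.integer(ceiling(n_scen * 0.7)) # 5/7, 9/12
    rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
      n <- counts$total[i]
      k <- counts$low[i]
      data.frame(
        clinician_id = paste0(substr(counts$group[i], 1, 3), "_",
                              seq_len(n)),
        group = counts$group[i],
        n_correct = c(rep(low_score, k), rep(high_score, n - k)),
        n_scenarios = n_scen, stringsAsFactors = FALSE)
    }))
    rows$low_scorer <- rows$n_correct / rows$n_scenarios <= 0.5
    rows
  }
  list(counts_7 = counts_7, counts_12 = counts_12, gender_7 = gender_7,
       gender_12 = gender_12,
       scorecards_7 = mk_cards(counts_7, 7L),
       scorecards_12 = mk_cards(counts_12, 12L))
}

#' Pilot-study record fixture
#'
#' The 58 pilot colonoscopies with category counts exactly as published:
#' 30 with stated and chart-confirmed agreement, 16 discordant, 4 where
#' stated agreement was contradicted by chart review (incorrect tool use),
#' 6 where the endoscopist recommended no follow-up because of patient
#' age, and 2 otherwise outside the tool's scope (hereditary syndrome /
#' anal cancer). Six endoscopists contributed 10, 10, 10, 10, 11, and 7
#' procedures. Direction labels on the 16 discordant records are a
#' reconstruction (11 shorter, 5 longer -- the published share of shorter
#' intervals is "most (70%)"); the endoscopist stated they would have
#' changed their recommendation on exactly 2 discordant records. The
#' record-level layout is synthetic; only the category counts are
#' published.
#'
#' @return A data frame of 58 records with columns `endoscopist_id`,
#'   `stated_agreement`, `chart_review_agreement`, `exclusion`,
#'   `direction`, `would_change`.
#' @export
table3_fixture <- function() {
  category <- c(rep("AGREE", 30L), rep("DISAGREE", 16L),
                rep("INCORRECT_TOOL_USE", 4L), rep("AGE_NO_FOLLOWUP", 6L),
                rep("NOT_APPLICABLE_OTHER", 2L))
  out <- data.frame(
    endoscopist_id = rep(paste0("E", 1:6),
                         times = c(10L, 10L, 10L, 10L, 11L, 7L)),
    stated_agreement = category %in% c("AGREE", "INCORRECT_TOOL_USE"),
    chart_review_agreement = ifelse(category == "AGREE", TRUE,
                                    ifelse(category == "INCORRECT_TOOL_USE",
                                           FALSE, NA)),
    exclusion = ifelse(category %in% c("AGREE", "DISAGREE"), "NONE",
                       category),
    direction = NA_character_, would_change = NA,
    stringsAsFactors = FALSE)
  disc <- which(category == "DISAGREE")
  out$direction[disc] <- c(rep("SHORTER", 11L), rep("LONGER", 5L))
  out$would_change[disc] <- c(TRUE, TRUE, rep(FALSE, 14L))
  out
}

#' Direction tally of incorrect scenario answers
#'
#' Synthetic stand-in for the direction split of incorrect answers in the
#' hypothetical-scenario audit, where a majority (58 percent) of errors
#' were longer than the guideline interval: 11 longer, 8 shorter. Only the
#' published percentage constrains it.
#'
#' @return Character vector of direction labels.
#' @export
scenario_direction_fixture <- function() {
  c(rep("LONGER", 11L), rep("SHORTER", 8L))
}
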