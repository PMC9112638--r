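# Declarative rule sets: the engine is interpretation of this table.

BOOL_FEATURES <- c("villous_present", "hgd_present", "ssp_dysplasia_present",
                   "tsa_present", "piecemeal_ge20")
NUM_FEATURES <- c("n_groups", "adenoma_count", "adenoma_max_size",
                  "serrated_count", "serrated_max_size", "hp_max_size",
                  "hp_rectosigmoid_max_size", "hp_proximal_max_size")

#' Load a surveillance rule set
#'
#' Reads a YAML rule-set file, validates it (schema, unique rule ids,
#' interval sanity, completeness of the surveillance step grid and the
#' post-resection sequence) and checks coverage: every single-group findings
#' signature on the bucketed grid of histology x count band x size band x
#' location x resection, plus the normal examination, must match at least
#' one index rule.
#'
#' @param path Path to a YAML file; `NULL` (default) loads the bundled
#'   CAG/USMSTF transcription.
#' @return An object of class `polypsurv_ruleset`.
#' @examples
#' rs <- load_ruleset()
#' length(rs$index_rules)
#' @export
load_ruleset <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ruleset-default.yaml",
                        package = "polypsurv", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  validate_ruleset(raw, path = path)
}

validate_ruleset <- function(raw, path = "<inline>") {
  for (sec in c("index_rules", "surveillance_step", "post_crc_sequence",
                "family_history_rules"))
    if (is.null(raw[[sec]]))
      fail("rule-set is missing section '", sec, "' (", path, ")")

  ids <- vapply(raw$index_rules, function(r) r$id %||% "", "")
  if (any(ids == "")) fail("every index rule needs an id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) fail("duplicate rule id: ", paste(unique(dup), collapse = ", "))

  as_range <- function(m, where) {
    m <- as.numeric(unlist(m))
    if (!is.numeric(m) || length(m) != 2L || anyNA(m) || m[1] > m[2] ||
        m[1] < 6 || m[2] > 120)
      fail("interval for ", where,
           " must be [min, max] months with 6 <= min <= max <= 120")
    interval_range(m[1], m[2])
  }

  rules <- lapply(raw$index_rules, function(r) {
    if (is.null(r$when) || !length(r$when))
      fail("rule '", r$id, "' has an empty predicate")
    for (feat in names(r$when)) {
      v <- r$when[[feat]]
      if (feat %in% BOOL_FEATURES) {
        if (!is_flag(v)) fail("rule '", r$id, "': condition on ", feat,
                              " must be TRUE/FALSE")
      } else if (feat %in% NUM_FEATURES) {
        v <- r$when[[feat]] <- as.numeric(unlist(v))
        if (!is.numeric(v) || length(v) != 2L || anyNA(v) || v[1] > v[2])
          fail("rule '", r$id, "': condition on ", feat,
               " must be a closed range [lo, hi]")
      } else fail("rule '", r$id, "': unknown feature '", feat, "'")
    }
    list(id = r$id, months = as_range(r$months, r$id), when = r$when)
  })
  names(rules) <- ids

  step <- raw$surveillance_step
  for (p in RISK_CLASSES) {
    if (is.null(step[[p]])) fail("surveillance_step is missing row ", p)
    for (q in RISK_CLASSES) {
      if (is.null(step[[p]][[q]]))
        fail("surveillance_step is missing cell (", p, ", ", q, ")")
      step[[p]][[q]] <- as_range(step[[p]][[q]], paste0("step ", p, "/", q))
    }
  }

  pcs <- raw$post_crc_sequence
  for (k in c("0", "1", "2plus")) {
    if (is.null(pcs[[k]])) fail("post_crc_sequence is missing key '", k, "'")
    pcs[[k]] <- as_range(pcs[[k]], paste0("post_crc ", k))
  }

  fh <- raw$family_history_rules
  for (k in c("high_risk_cap_months", "low_risk_cap_months"))
    if (!is_count1(fh[[k]] %||% NA) || fh[[k]] < 6 || fh[[k]] > 120)
      fail("family_history_rules$", k, " must be an integer in [6, 120]")

  rs <- structure(list(name = raw$name %||% "unnamed",
                       version = raw$version %||% 0L,
                       index_rules = rules, surveillance_step = step,
                       post_crc_sequence = pcs, family_history_rules = fh,
                       options = raw$options %||% list(),
                       source = path),
                  class = "polypsurv_ruleset")
  check_coverage(rs)
  rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The bucketed signature grid the coverage guarantee is stated over: one
# polyp group per signature plus the normal exam. Band representatives sit
# strictly inside each band so closed rule bounds behave identically for
# every member of the band.
coverage_grid <- function() {
  sig <- expand.grid(histology = HISTOLOGIES, count = c(1L, 2L, 4L, 6L, 12L),
                     size = c(5L, 12L, 22L), location = LOCATIONS,
                     resection = RESECTIONS, stringsAsFactors = FALSE)
  c(list(colonoscopy_findings()),
    lapply(seq_len(nrow(sig)), function(i)
      colonoscopy_findings(list(polyp_group(
        sig$histology[i], sig$count[i], sig$size[i],
        sig$location[i], sig$resection[i])))))
}

check_coverage <- function(rs) {
  for (f in coverage_grid()) {
    m <- match_index_rules(rs, f)
    if (!length(m)) {
      g <- f$polyp_groups
      sig <- if (!length(g)) "normal exam"
      else paste(g[[1L]]$count, "x", g[[1L]]$histology, g[[1L]]$max_size_mm,
                 "mm", g[[1L]]$location, g[[1L]]$resection)
      fail("rule set does not cover findings signature: ", sig)
    }
  }
  invisible(rs)
}

#' @export
print.polypsurv_ruleset <- function(x, ...) {
  cat("<polypsurv_ruleset> '", x$name, "' v", x$version, ": ",
      length(x$index_rules), " index rules, 3x3 surveillance step grid, ",
      "post-CRC sequence, family-history caps ",
      x$family_history_rules$high_risk_cap_months, "/",
      x$family_history_rules$low_risk_cap_months, " mo\n", sep = "")
  invisible(x)
}
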