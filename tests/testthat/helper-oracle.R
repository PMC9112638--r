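# Independent oracles, deliberately implemented without the package's
# feature/predicate machinery.

# Brute-force index evaluator: each default rule hand-coded from the rule
# table, evaluated independently; combination is the elementwise minimum.
oracle_index_interval <- function(findings) {
  g <- findings$polyp_groups
  hist <- vapply(g, function(x) x$histology, "")
  cnt <- vapply(g, function(x) x$count, 0L)
  sz <- vapply(g, function(x) x$max_size_mm, 0L)
  loc <- vapply(g, function(x) x$location, "")
  res <- vapply(g, function(x) x$resection, "")
  aden <- hist %in% c("TUBULAR_ADENOMA", "TUBULOVILLOUS_OR_VILLOUS",
                      "ADENOMA_HGD")
  ser <- hist %in% c("SSP", "SSP_DYSPLASIA")
  hp <- hist == "HYPERPLASTIC"
  na_ <- sum(cnt[aden])
  amax <- if (any(aden)) max(sz[aden]) else 0L
  ns <- sum(cnt[ser])
  smax <- if (any(ser)) max(sz[ser]) else 0L
  cand <- list()
  add <- function(lo, hi) cand[[length(cand) + 1L]] <<- c(lo, hi)
  if (length(g) == 0L) add(120, 120)
  if (na_ >= 1 && na_ <= 2 && amax < 10) add(84, 120)
  if (na_ >= 3 && na_ <= 4 && amax < 10) add(36, 60)
  if (na_ >= 5 && na_ <= 10) add(36, 36)
  if (amax >= 10) add(36, 36)
  if (any(hist == "TUBULOVILLOUS_OR_VILLOUS")) add(36, 36)
  if (any(hist == "ADENOMA_HGD")) add(36, 36)
  if (na_ > 10) add(12, 12)
  if (ns >= 1 && ns <= 2 && smax < 10) add(60, 120)
  if (ns >= 3 && ns <= 4 && smax < 10) add(36, 60)
  if (ns >= 5) add(36, 36)
  if (smax >= 10) add(36, 36)
  if (any(hist == "SSP_DYSPLASIA")) add(36, 36)
  if (any(hist == "TSA")) add(36, 36)
  if (any(hp & sz >= 10)) add(36, 60)
  if (any(hp & sz < 10 & loc == "RECTOSIGMOID")) add(120, 120)
  if (any(hp & sz < 10 & loc != "RECTOSIGMOID")) add(60, 120)
  if (any(res == "PIECEMEAL" & sz >= 20)) add(6, 6)
  if (!length(cand)) stop("oracle: uncovered signature")
  m <- do.call(rbind, cand)
  c(min(m[, 1]), min(m[, 2]))
}

# Naive r x 2 enumeration via sequential hypergeometric masses
# (stats::dhyper), a different arithmetic route than the package's exact
# integer numerators.
oracle_enumerate <- function(row_margins, c1) {
  r <- length(row_margins)
  N <- sum(row_margins)
  out_k <- list()
  out_p <- numeric()
  rec <- function(i, rem, cur, p) {
    if (i > r) {
      if (rem == 0L) {
        out_k[[length(out_k) + 1L]] <<- cur
        out_p[length(out_p) + 1L] <<- p
      }
      return(invisible())
    }
    rest <- sum(row_margins[-seq_len(i)])
    for (k in max(0L, rem - rest):min(row_margins[i], rem)) {
      pk <- stats::dhyper(k, row_margins[i], rest + 0L,
                          rem)
      if (i == r) pk <- as.numeric(k == rem)
      rec(i + 1L, rem - k, c(cur, k), p * pk)
    }
    invisible()
  }
  rec(1L, as.integer(c1), integer(), 1)
  list(k = do.call(rbind, out_k), p = out_p)
}

oracle_freeman_halton <- function(tab) {
  en <- oracle_enumerate(rowSums(tab), sum(tab[, 1]))
  obs <- tab[, 1]
  p_obs <- en$p[apply(en$k, 1, function(k) all(k == obs))]
  sum(en$p[en$p <= p_obs * (1 + 1e-9)])
}

oracle_fisher_min_tail <- function(tab) {
  R <- rowSums(tab)
  c1 <- sum(tab[, 1])
  k_obs <- tab[1, 1]
  lower <- stats::phyper(k_obs, c1, sum(tab) - c1, R[1])
  upper <- stats::phyper(k_obs - 1, c1, sum(tab) - c1, R[1],
                         lower.tail = FALSE)
  min(lower, upper)
}

random_r_by_2 <- function(max_total = 30L, min_rows = 2L, max_rows = 5L) {
  repeat {
    r <- min_rows + sample.int(max_rows - min_rows + 1L, 1L) - 1L
    m <- matrix(stats::rpois(2L * r, 2), nrow = r)
    if (sum(m) >= 1 && sum(m) <= max_total && all(rowSums(m) > 0) &&
        all(colSums(m) > 0))
      return(m)
  }
}

# random single polyp group / findings for property tests
random_group <- function() {
  polyp_group(sample(c("TUBULAR_ADENOMA", "TUBULOVILLOUS_OR_VILLOUS",
                       "ADENOMA_HGD", "SSP", "SSP_DYSPLASIA", "TSA",
                       "HYPERPLASTIC"), 1L),
              sample(1:13, 1L), sample(c(1:9, 10:19, 20:30), 1L),
              sample(c("RECTOSIGMOID", "PROXIMAL", "UNKNOWN"), 1L),
              sample(c("COMPLETE_ENBLOC", "PIECEMEAL", "INCOMPLETE"), 1L))
}
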