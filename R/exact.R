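# Exact inference on r x 2 contingency tables by complete enumeration under
# fixed margins. Table probabilities are multivariate hypergeometric:
#
#   P(table) = prod_i C(R_i, n_i1) / C(N, C_1)
#
# All tables sharing the margins share the denominator C(N, C_1), so every
# probability is carried as an exact integer numerator; tie detection in the
# two-sided sums is exact integer comparison whenever C(N, C_1) < 2^53
# (true for every audit-sized table), with a 1e-12 relative tolerance kept
# as the documented tie rule for larger tables where numerators leave the
# exactly-representable integer range.

TIE_RTOL <- 1e-12

#' An r x 2 contingency table of group counts
#'
#' @param x A matrix with 2 columns, or a data frame whose last two columns
#'   are the low/high counts (an optional first character column supplies
#'   row labels).
#' @param drop_empty Drop rows whose total is zero (e.g. a clinician group
#'   absent from one battery) before testing. Default `TRUE`.
#' @return An object of class `contingency_table`: an integer matrix with
#'   row labels.
#' @examples
#' contingency_table(rbind(c(6, 7), c(3, 3)))
#' @export
contingency_table <- function(x, drop_empty = TRUE) {
  if (is.data.frame(x)) {
    labels <- if (is.character(x[[1L]]) || is.factor(x[[1L]]))
      as.character(x[[1L]]) else NULL
    num <- x[vapply(x, is.numeric, NA)]
    if (ncol(num) != 2L) fail("need exactly two count columns")
    x <- as.matrix(num)
    if (!is.null(labels)) rownames(x) <- labels
  }
  if (!is.matrix(x) || ncol(x) != 2L) fail("x must be an r x 2 matrix")
  if (any(x < 0) || any(x != round(x))) fail("counts must be integers >= 0")
  storage.mode(x) <- "integer"
  if (drop_empty) x <- x[rowSums(x) > 0, , drop = FALSE]
  if (nrow(x) < 1L || sum(x) < 1L) fail("table needs a positive grand total")
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  structure(x, class = c("contingency_table", class(x)))
}

as_ct <- function(x) {
  if (inherits(x, "contingency_table")) x else contingency_table(x)
}

#' Enumerate every table with the observed margins
#'
#' Yields every non-negative integer r x 2 matrix with the given row and
#' column margins, as the matrix of first-column count vectors, together
#' with the exact probability numerators (common denominator
#' `choose(N, c1)`).
#'
#' @param row_margins Integer vector of row totals.
#' @param col_margins Integer vector of length 2 (column totals).
#' @param max_tables Hard cap on the enumeration size; exceeding it is an
#'   error, never a silent approximation.
#' @return A list with `k` (matrix, one row per table), `numerators`,
#'   `denominator`.
#' @examples
#' enumerate_tables(c(13, 6), c(9, 10))$k
#' @export
enumerate_tables <- function(row_margins, col_margins, max_tables = 1e6) {
  R <- as.integer(row_margins)
  cm <- as.integer(col_margins)
  if (length(cm) != 2L || any(R < 0) || any(cm < 0) || sum(R) != sum(cm))
    fail("inconsistent margins")
  r <- length(R)
  tail_sums <- rev(cumsum(rev(R)))  # sum of R[i..r]
  acc <- vector("list", 1024L)
  n_acc <- 0L
  rec <- function(i, rem, cur) {
    if (i > r) {
      n_acc <<- n_acc + 1L
      if (n_acc > max_tables)
        fail("enumeration exceeds max_tables = ", max_tables)
      acc[[n_acc]] <<- cur
      return(invisible())
    }
    rest <- if (i < r) tail_sums[i + 1L] else 0L
    lo <- max(0L, rem - rest)
    hi <- min(R[i], rem)
    for (k in lo:hi) rec(i + 1L, rem - k, c(cur, k))
    invisible()
  }
  rec(1L, cm[1L], integer())
  ks <- do.call(rbind, acc[seq_len(n_acc)])
  numer <- vapply(seq_len(nrow(ks)), function(j)
    prod(choose(R, ks[j, ])), 0)
  list(k = ks, numerators = numer, denominator = choose(sum(R), cm[1L]))
}

table_numerator <- function(tab) prod(choose(rowSums(tab), tab[, 1L]))

#' Conditional probability of a table given its margins
#'
#' The multivariate hypergeometric mass of the observed table under fixed
#' row and column margins. A table with a zero column is the unique table
#' with those margins and has probability 1.
#'
#' @param table An r x 2 matrix, data frame, or [contingency_table()].
#' @return A probability in (0, 1].
#' @examples
#' table_probability(rbind(c(6, 7), c(3, 3))) # 10080/27132
#' @export
table_probability <- function(table) {
  tab <- as_ct(table)
  if (any(colSums(tab) == 0L)) return(1)
  table_numerator(tab) / choose(sum(tab), sum(tab[, 1L]))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' `ONE_SIDED_MIN_TAIL` (the audit default) is the smaller of the lower and
#' upper tail probabilities of the top-left cell, inclusive of the observed
#' table -- the tail pointing in the direction of the observed deviation.
#' `TWO_SIDED` sums the probabilities of all margin-consistent tables whose
#' probability does not exceed that of the observed table.
#'
#' @param table A 2 x 2 count matrix, data frame, or [contingency_table()]
#'   (rows with zero totals are dropped first; exactly two informative rows
#'   are required).
#' @param alternative `"ONE_SIDED_MIN_TAIL"` or `"TWO_SIDED"`.
#' @return The exact p-value.
#' @examples
#' fisher_2x2(rbind(c(6, 7), c(3, 3)))                  # 0.630...
#' fisher_2x2(rbind(c(3, 2), c(2, 3)), "TWO_SIDED")     # 1
#' @export
fisher_2x2 <- function(table,
                       alternative = c("ONE_SIDED_MIN_TAIL", "TWO_SIDED")) {
  alternative <- match.arg(alternative)
  tab <- as_ct(table)
  if (nrow(tab) != 2L)
    fail("fisher_2x2 requires exactly 2 informative rows; got ", nrow(tab))
  if (any(colSums(tab) == 0L)) return(1)
  en <- enumerate_tables(rowSums(tab), colSums(tab))
  k_obs <- tab[1L, 1L]
  num <- en$numerators
  ks <- en$k[, 1L]
  if (alternative == "ONE_SIDED_MIN_TAIL") {
    lower <- sum(num[ks <= k_obs])
    upper <- sum(num[ks >= k_obs])
    min(lower, upper) / en$denominator
  } else {
    n_obs <- num[ks == k_obs]
    sum(num[num <= n_obs * (1 + TIE_RTOL)]) / en$denominator
  }
}

#' Freeman-Halton exact test on an r x 2 table
#'
#' The extension of Fisher's exact test to more than two groups: all tables
#' with the observed margins are enumerated and the p-value is the total
#' probability of tables no more probable than the observed one (inclusive;
#' ties detected exactly, with a 1e-12 relative guard). On two rows this
#' reduces to the two-sided 2 x 2 test by definition.
#'
#' @param table An r x 2 count matrix, data frame, or [contingency_table()].
#' @param max_tables Enumeration cap, forwarded to [enumerate_tables()].
#' @return The exact p-value.
#' @examples
#' freeman_halton(rbind(c(2, 3), c(2, 2), c(3, 1), c(3, 3))) # 0.8636...
#' @export
freeman_halton <- function(table, max_tables = 1e6) {
  tab <- as_ct(table)
  if (nrow(tab) < 2L) fail("need at least 2 informative rows")
  if (any(colSums(tab) == 0L)) return(1)
  en <- enumerate_tables(rowSums(tab), colSums(tab), max_tables = max_tables)
  n_obs <- table_numerator(tab)
  sum(en$numerators[en$numerators <= n_obs * (1 + TIE_RTOL)]) /
    en$denominator
}
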