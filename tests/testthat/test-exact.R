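test_that("table probability is the multivariate hypergeometric mass", {
  expect_equal(table_probability(rbind(c(6, 7), c(3, 3))), 10080 / 27132,
               tolerance = 1e-14)
  # forced diagonal with margins 5/5, 5/5
  expect_equal(table_probability(rbind(c(5, 0), c(0, 5))), 1 / 252,
               tolerance = 1e-14)
  # a zero column leaves a unique table
  expect_equal(table_probability(rbind(c(4, 0), c(2, 0))), 1)
})

test_that("enumeration yields every margin-consistent table exactly once", {
  en <- enumerate_tables(c(13, 6), c(9, 10))
  expect_equal(nrow(en$k), 7L)            # k = 3..9
  expect_setequal(en$k[, 1], 3:9)
  expect_equal(sum(en$numerators) / en$denominator, 1, tolerance = 1e-12)
  en2 <- enumerate_tables(c(5, 5), c(5, 5))
  expect_equal(nrow(en2$k), 6L)           # k = 0..5
  expect_error(enumerate_tables(c(5, 5), c(5, 6)), "inconsistent")
  expect_error(enumerate_tables(c(20, 20, 20), c(30, 30), max_tables = 5),
               "max_tables")
})

test_that("2x2 tests reproduce the published audit p-values", {
  expect_equal(round(fisher_2x2(rbind(c(6, 7), c(3, 3))), 2), 0.63)
  expect_equal(fisher_2x2(rbind(c(6, 7), c(3, 3))), 17094 / 27132,
               tolerance = 1e-14)
  expect_equal(fisher_2x2(rbind(c(3, 2), c(2, 3))), 0.5, tolerance = 1e-14)
  expect_equal(fisher_2x2(rbind(c(3, 2), c(2, 3)), "TWO_SIDED"), 1,
               tolerance = 1e-14)
  expect_error(fisher_2x2(rbind(c(1, 1), c(1, 1), c(1, 1))), "2 informative")
  # zero-total rows are dropped before testing
  expect_equal(fisher_2x2(rbind(c(6, 7), c(0, 0), c(3, 3))),
               fisher_2x2(rbind(c(6, 7), c(3, 3))))
})

test_that("Freeman-Halton matches its published values and reduces on 2 rows", {
  expect_equal(round(freeman_halton(rbind(c(2, 3), c(2, 2), c(3, 1),
                                          c(3, 3))), 2), 0.86)
  expect_equal(freeman_halton(rbind(c(2, 2), c(2, 2), c(1, 1))), 1,
               tolerance = 1e-14)
  set.seed(99)
  for (i in 1:25) {
    m <- random_r_by_2(max_rows = 2L)
    expect_equal(freeman_halton(m), fisher_2x2(m, "TWO_SIDED"),
                 tolerance = 1e-14)
  }
})

test_that("shipped tests agree with the naive enumeration oracle to 1e-12", {
  set.seed(314)
  for (i in 1:120) {
    m <- random_r_by_2(max_total = 30L)
    expect_equal(freeman_halton(m), oracle_freeman_halton(m),
                 tolerance = 1e-12, info = paste("table", i))
    if (nrow(m) == 2L) {
      expect_equal(fisher_2x2(m), oracle_fisher_min_tail(m),
                   tolerance = 1e-12)
      # independent cross-check against the standard library implementation
      expect_equal(fisher_2x2(m, "TWO_SIDED"),
                   stats::fisher.test(m)$p.value, tolerance = 1e-6)
    }
  }
})

test_that("p-values lie in (0, 1], two-sided dominates min-tail, permutations irrelevant", {
  set.seed(2718)
  for (i in 1:60) {
    m <- random_r_by_2()
    p <- freeman_halton(m)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(freeman_halton(m[sample(nrow(m)), , drop = FALSE]), p,
                 tolerance = 1e-12)
    if (nrow(m) == 2L) {
      p1 <- fisher_2x2(m)
      p2 <- fisher_2x2(m, "TWO_SIDED")
      expect_gte(p2, p1 - 1e-14)
      expect_equal(fisher_2x2(m[, 2:1], "TWO_SIDED"), p2, tolerance = 1e-12)
      expect_equal(fisher_2x2(m[2:1, ], "TWO_SIDED"), p2, tolerance = 1e-12)
    }
  }
})
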