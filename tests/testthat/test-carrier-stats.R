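test_that("two-sided Fisher p reproduces the published pairwise comparisons", {
  expect_equal(round(fisher_exact_two_sided(matrix(c(1, 43, 1, 1024), 2, byrow = TRUE)), 3),
               0.081)
  expect_equal(round(fisher_exact_two_sided(matrix(c(1, 437, 0, 1025), 2, byrow = TRUE)), 3),
               0.299)
  expect_lt(fisher_exact_two_sided(matrix(c(15, 423, 1, 1024), 2, byrow = TRUE)),
            0.0001)
})

test_that("a zero carrier margin gives p = 1 and a negative cell errors", {
  expect_equal(fisher_exact_two_sided(matrix(c(0, 44, 0, 1025), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 4, 1, 4), 2, byrow = TRUE)),
               "negative")
})

test_that("Fisher p agrees with enumeration and with stats::fisher.test on random tables", {
  set.seed(31)
  for (cells in random_tables(400)) {
    m <- matrix(cells, 2, byrow = TRUE)
    p <- fisher_exact_two_sided(m)
    expect_equal(p, enum_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10,
                 label = paste("table", paste(cells, collapse = ",")))
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("two-sided p dominates the one-sided p and respects symmetry", {
  set.seed(32)
  for (cells in random_tables(100)) {
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p2 <- fisher_exact_two_sided(matrix(cells, 2, byrow = TRUE))
    # one-sided p in the direction of the observed deviation: the smaller
    # of the enrichment and depletion tails
    p1 <- min(carrierscan:::fisher_one_sided_ge(a, b, c, d),
              carrierscan:::fisher_one_sided_ge(c, d, a, b))
    expect_gte(p2, p1 - 1e-12)
    # swapping rows together with columns leaves p unchanged
    p2_swap <- fisher_exact_two_sided(matrix(c(d, c, b, a), 2, byrow = TRUE))
    expect_equal(p2, p2_swap, tolerance = 1e-12)
  }
})

test_that("moving a carrier into cases never increases the one-sided enrichment p", {
  for (m in c(5, 10)) {
    for (n in c(8, 15)) {
      for (K in 1:4) {
        a <- max(0, K - n):min(K, m)
        p <- vapply(a, function(ai) {
          carrierscan:::fisher_one_sided_ge(ai, m - ai, K - ai, n - (K - ai))
        }, numeric(1))
        expect_true(all(diff(p) <= 1e-12))
      }
    }
  }
})

test_that("carrier frequencies format as published", {
  expect_equal(carrier_frequency(1, 44)$percent, 2.3)
  expect_equal(carrier_frequency(1, 44)$label, "1/44 (2.3)")
  expect_equal(carrier_frequency(15, 438)$percent, 3.4)
  expect_equal(carrier_frequency(0, 56)$percent, 0)
  expect_error(carrier_frequency(1, 0), "positive")
  expect_error(carrier_frequency(5, 4), "exceed")
})

test_that("pairwise tests reproduce the published comparison table cell by cell", {
  co <- generate_cohort(table2_cohort_spec(), seed = 2)
  pairs <- data.frame(case_group = c("oc_families", "hboc_families", "sporadic_oc"),
                      control_group = "seq_controls", stringsAsFactors = FALSE)
  res <- pairwise_case_control_tests(co, pairs)
  cell <- function(v, g) res[res$variant_id == v & res$case_group == g, ]

  r <- cell("RAD51C:c.414G>C", "oc_families")
  expect_equal(r$case_carriers, 1L); expect_equal(r$case_denominator, 44L)
  expect_equal(r$case_percent, 2.3)
  expect_equal(round(r$p_two_sided, 3), 0.081)

  r <- cell("RAD51D:c.620C>T", "sporadic_oc")
  expect_equal(r$case_percent, 3.4)
  expect_lt(r$p_two_sided, 0.0001)

  expect_equal(round(cell("RAD51C:c.705G>T", "sporadic_oc")$p_two_sided, 3), 0.299)
  expect_equal(round(cell("RAD51D:c.137C>G", "sporadic_oc")$p_two_sided, 3), 0.299)
  expect_equal(round(cell("RAD51D:c.694C>T", "sporadic_oc")$p_two_sided, 3), 0.299)

  # familial denominators count families, not recruited participants
  expect_true(all(res$case_denominator[res$case_group == "oc_families"] == 44L))

  # every cell equals a manual Fisher call on its own 2x2 table
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    if (is.na(r$case_carriers)) next
    manual <- fisher_exact_two_sided(matrix(
      c(r$case_carriers, r$case_denominator - r$case_carriers,
        r$control_carriers, r$control_denominator - r$control_carriers),
      2, byrow = TRUE))
    expect_equal(r$p_two_sided, manual)
  }
})

test_that("a variant with no carriers anywhere tests at p = 1 with zero frequency", {
  spec <- table2_cohort_spec()
  spec$carriers$carriers[spec$carriers$variant_id == "RAD51C:c.705G>T"] <- 0L
  co <- generate_cohort(spec, seed = 3)
  res <- pairwise_case_control_tests(
    co, data.frame(case_group = "sporadic_oc", control_group = "seq_controls"),
    variants = "RAD51C:c.705G>T")
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$carrier_freq_case, 0)
})

test_that("not-assayed group x variant pairs yield NA rows, not tests", {
  co <- generate_cohort(table2_cohort_spec(), seed = 5)
  res <- pairwise_case_control_tests(
    co, data.frame(case_group = "sporadic_oc", control_group = "geno_controls"),
    variants = "RAD51C:c.705G>T")
  expect_true(is.na(res$p_two_sided))
  expect_true(is.na(res$control_carriers))
})

test_that("the discovery-phase carrier summary matches the published percentages", {
  co <- generate_cohort(phase1_cohort_spec(), seed = 6)
  s <- carrier_summary(co)
  fam <- s[s$group == "oc_families_phase1", ]
  spor <- s[s$group == "sporadic_early_onset", ]
  expect_equal(fam$label, "3/17 (17.6)")
  expect_equal(spor$label, "6/53 (11.3)")
})
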