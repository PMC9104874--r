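test_that("exact-count cohorts reproduce their specification with probability 1", {
  spec <- table2_cohort_spec()
  for (seed in c(1, 2, 3)) {
    co <- generate_cohort(spec, seed = seed)
    expect_equal(co$carriers, spec$carriers)
    expect_equal(co$groups, spec$groups)
  }
  # assignments never place one unit on two variants
  co <- generate_cohort(spec, seed = 4)
  asg <- attr(co, "carrier_assignments")
  expect_false(anyDuplicated(asg[, c("group", "unit")]) > 0)
})

test_that("generators are pure functions of spec and seed", {
  a <- generate_cohort(table2_cohort_spec(), seed = 17)
  b <- generate_cohort(table2_cohort_spec(), seed = 17)
  expect_identical(a$participants, b$participants)
  expect_identical(generate_variant_panel(40, seed = 17),
                   generate_variant_panel(40, seed = 17))
  expect_identical(generate_loh_observations(c(0.5, 0.9), seed = 17),
                   generate_loh_observations(c(0.5, 0.9), seed = 17))
  arms <- data.frame(variant_id = "V", n = 5L, age_mean = 58.5,
                     age_sd = 9, survival_mean = 80)
  expect_identical(generate_clinical_table(arms, seed = 17),
                   generate_clinical_table(arms, seed = 17))
})

test_that("the duplicate-membership arithmetic is forced by the spec", {
  spec <- table2_cohort_spec()
  co <- generate_cohort(spec, seed = 23)
  expect_equal(nrow(co$participants), sum(spec$groups$n_participants) - 9L)
})

test_that("probability-mode carrier counts are binomial draws within denominators", {
  spec <- table2_cohort_spec()
  spec$carriers <- data.frame(group = c("sporadic_oc", "seq_controls"),
                              variant_id = "RAD51D:c.620C>T",
                              prob = c(15 / 438, 1 / 1025),
                              stringsAsFactors = FALSE)
  set.seed(61)
  counts <- replicate(50, {
    co <- generate_cohort(spec)
    carrierscan:::carrier_count(co$carriers, "sporadic_oc", "RAD51D:c.620C>T")
  })
  expect_true(all(counts >= 0 & counts <= 438))
  expect_gt(mean(counts), 15 * 0.5)   # crude scale check on the binomial mean
  expect_lt(mean(counts), 15 * 1.7)
})

test_that("an infeasible carrier specification errors", {
  spec <- table2_cohort_spec()
  spec$carriers$carriers[spec$carriers$group == "oc_families"] <- 11L  # 55 > 44 families
  expect_error(generate_cohort(spec, seed = 1), "infeasible|denominator")
})

test_that("sub-threshold decoys are fully rejected and the planted panel recovered", {
  panel <- generate_variant_panel(200, seed = 1)
  res <- filter_and_prioritize(panel)
  expect_setequal(res$candidates$variant_id, table1_variants()$variant_id)
})

test_that("a panel with no planted variants yields no candidates", {
  panel <- generate_variant_panel(100, planted = table1_variants()[0, ], seed = 2)
  expect_equal(nrow(filter_and_prioritize(panel)$candidates), 0L)
})

test_that("decoys drawn entirely above the MAF cut all fall at the frequency filter", {
  panel <- generate_variant_panel(100, planted = table1_variants()[0, ],
                                  maf_common_fraction = 1,
                                  maf_missing_fraction = 0, seed = 3)
  res <- apply_class_and_frequency_filters(panel)
  expect_equal(nrow(res$kept), 0L)
  expect_true(all(res$trace$first_fail %in%
                    c("common_in_reference", "silent_or_intronic")))
  expect_true(all(res$trace$first_fail[res$trace$class_pass] == "common_in_reference"))
})

test_that("straddling decoys degrade recovery in a controlled way", {
  panel <- generate_variant_panel(200, decoy_mode = "straddling", seed = 4)
  res <- filter_and_prioritize(panel)
  expect_true(all(table1_variants()$variant_id %in% res$candidates$variant_id))
  # some decoys now cross the thresholds
  expect_gt(nrow(res$candidates), 5L)
})

test_that("synthetic LOH observations track the purity decision boundary", {
  # complete loss is recoverable iff 1/(2-p) > 0.90, i.e. p > 8/9
  purities <- rep(seq(0.70, 1.00, by = 0.02), each = 40)
  obs <- generate_loh_observations(purities, "wild_type_loss",
                                   depth = 5000L, seed = 7)
  calls <- call_loh(obs)
  rate <- tapply(calls$state == "complete_loss", obs$purity, mean)
  boundary <- 8 / 9
  expect_true(all(rate[as.numeric(names(rate)) > boundary + 0.02] > 0.95))
  expect_true(all(rate[as.numeric(names(rate)) < boundary - 0.02] < 0.05))
})

test_that("high-depth extremes pin the simulated fractions", {
  top <- generate_loh_observations(1, "wild_type_loss", depth = 10000L, seed = 8)
  expect_gt(top$tumour_vaf, 0.99)
  null <- generate_loh_observations(0, "wild_type_loss", depth = 10000L, seed = 9)
  expect_lt(abs(null$tumour_vaf - 0.5), 0.02)
})

test_that("synthetic clinical ages respect the truncation window", {
  arms <- data.frame(variant_id = "V", n = 400L, age_mean = 58.5,
                     age_sd = 9, survival_mean = 80)
  clin <- generate_clinical_table(arms, seed = 10)
  expect_true(all(clin$age_at_diagnosis >= 25 & clin$age_at_diagnosis <= 90))
  expect_lt(abs(mean(clin$age_at_diagnosis) - 58.5), 1.5)
  expect_true(all(clin$survival_months >= 0))
})
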