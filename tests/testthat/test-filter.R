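make_calls <- function(depth, vaf, qual = TRUE) {
  data.frame(sample_id = sprintf("S%03d", seq_along(depth)),
             variant_id = rep("V1", length(depth)), depth = depth, vaf = vaf,
             base_quality_pass = rep_len(qual, length(depth)),
             stringsAsFactors = FALSE)
}

test_that("quality filters apply the coverage and VAF rules with inclusive bounds", {
  calls <- make_calls(depth = c(9L, 10L, 30L, 30L, 30L, 30L),
                      vaf = c(0.50, 0.50, 0.20, 0.80, 0.19, 0.81))
  res <- apply_quality_filters(calls)
  expect_equal(res$trace$status,
               c("excluded", "kept", "kept", "kept", "excluded", "excluded"))
  expect_equal(res$trace$first_fail[1], "low_coverage")
  expect_equal(res$trace$first_fail[5], "vaf_window")
  # failed base quality excludes regardless of depth/VAF
  bad <- apply_quality_filters(make_calls(30L, 0.5, qual = FALSE))
  expect_equal(bad$trace$status, "excluded")
  # empty input is not an error
  expect_equal(nrow(apply_quality_filters(make_calls(integer(0), numeric(0)))$kept), 0L)
})

test_that("quality filtering equals direct predicate reapplication on random calls", {
  set.seed(101)
  calls <- make_calls(depth = sample(0:40, 300, replace = TRUE),
                      vaf = round(runif(300), 2),
                      qual = sample(c(TRUE, FALSE), 300, replace = TRUE,
                                    prob = c(0.9, 0.1)))
  cfg <- filter_config()
  res <- apply_quality_filters(calls, cfg)
  oracle <- calls$depth >= 10 & calls$vaf >= 0.20 & calls$vaf <= 0.80 &
    calls$base_quality_pass
  expect_equal(res$kept, calls[oracle, ])
})

test_that("class and frequency filters drop silent/intronic and common variants but keep missing MAF", {
  panel <- table1_variants()[rep(1, 4), ]
  panel$variant_id <- sprintf("V%d", 1:4)
  panel$consequence <- c("missense", "missense", "silent", "intronic")
  panel$maf_reference <- c(0.02, NA, 0.000001, 0.000001)
  res <- apply_class_and_frequency_filters(panel)
  expect_equal(res$trace$status, c("excluded", "kept", "excluded", "excluded"))
  expect_equal(res$trace$first_fail, c("common_in_reference", NA,
                                       "silent_or_intronic", "silent_or_intronic"))
  # the packaged panel (all MAF <= 0.0001) passes untouched
  full <- apply_class_and_frequency_filters(table1_variants())
  expect_equal(nrow(full$kept), 5L)
})

test_that("MAF exactly at the threshold is excluded and just below is kept", {
  panel <- table1_variants()[c(1, 1), ]
  panel$variant_id <- c("Va", "Vb")
  panel$maf_reference <- c(0.01, 0.0099999)
  res <- apply_class_and_frequency_filters(panel)
  expect_equal(res$trace$status, c("excluded", "kept"))
})

test_that("in-silico support follows the any-tool rule with the splice consensus", {
  panel <- table1_variants()
  # the splice-donor variant: conserved x3, CADD damaging, 4 splice tools affecting
  v705 <- panel[panel$variant_id == "RAD51C:c.705G>T", ]
  sup <- evaluate_insilico_support(v705)
  expect_true(sup$supported)
  expect_true(all(c("CADD_phred", "splice_consensus") %in% sup$evidence))

  # everything failing or missing: no support
  none <- v705
  none[, unlist(predictor_tools())] <- NA
  none$REVEL <- "benign"
  expect_false(evaluate_insilico_support(none)$supported)

  # inclusive score thresholds: REVEL exactly 0.4 counts as damaging
  edge <- none
  edge$REVEL <- "0.4"
  expect_true(evaluate_insilico_support(edge)$supported)
  edge$REVEL <- "0.3999"
  expect_false(evaluate_insilico_support(edge)$supported)
})

test_that("the splice consensus requires two agreeing tools", {
  base <- table1_variants()[1, ]
  base[, unlist(predictor_tools())] <- NA
  ada_only <- base; ada_only$dbscSNV_ADA <- "0.9"
  expect_false(evaluate_insilico_support(ada_only)$supported)
  both <- ada_only; both$dbscSNV_RF <- "0.41"
  expect_true(evaluate_insilico_support(both)$supported)
  mes_only <- base; mes_only$MaxEntScan_class <- "affecting_splicing"
  expect_false(evaluate_insilico_support(mes_only)$supported)
  mes_hsf <- mes_only; mes_hsf$HSF_class <- "affecting_splicing"
  expect_true(evaluate_insilico_support(mes_hsf)$supported)
})

test_that("PROVEAN direction is configurable and defaults to the tool convention", {
  base <- table1_variants()[1, ]
  base[, unlist(predictor_tools())] <- NA
  base$PROVEAN <- "-3.1"
  expect_true(evaluate_insilico_support(base)$supported)   # <= -2.5 damaging
  base$PROVEAN <- "1.0"
  expect_false(evaluate_insilico_support(base)$supported)
  cfg <- filter_config(provean_direction = "ge")
  expect_true(evaluate_insilico_support(base, cfg)$supported)
})

test_that("prioritization recovers exactly the five-variant founder panel", {
  res <- prioritize_candidates(table1_variants())
  expect_setequal(res$candidates$variant_id,
                  c("RAD51C:c.414G>C", "RAD51C:c.705G>T", "RAD51D:c.137C>G",
                    "RAD51D:c.620C>T", "RAD51D:c.694C>T"))
  expect_equal(nrow(res$candidates) + sum(res$trace$status == "excluded"),
               nrow(table1_variants()))
})

test_that("benign missense variants are excluded even with damaging predictors", {
  v <- table1_variants()[1, ]  # all-damaging missense profile
  v$clinvar_class <- "benign"; v$acmg_class <- "benign"
  res <- prioritize_candidates(v)
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(res$trace$first_fail, "clinical_class")
  # but a conflicting record is accepted as VUS-equivalent
  v$clinvar_class <- "conflicting"
  expect_equal(nrow(prioritize_candidates(v)$candidates), 1L)
})

test_that("loss-of-function variants are candidates regardless of predictors", {
  v <- table1_variants()[5, ]  # nonsense
  v$clinvar_class <- "not_reported"; v$acmg_class <- "not_reported"
  v[, unlist(predictor_tools())] <- NA
  expect_equal(nrow(prioritize_candidates(v)$candidates), 1L)
})

test_that("prioritization equals an independent predicate on randomized panels", {
  cfg <- filter_config()
  thr <- cfg$thresholds
  # independent rule, written directly from the selection criteria
  oracle_support <- function(row) {
    val <- function(tool) {
      cell <- row[[tool]]
      if (is.na(cell)) return(NA)
      if (cell %in% c("conserved", "damaging", "pathogenic", "affecting_splicing")) return(TRUE)
      if (cell %in% c("not_conserved", "tolerated", "benign", "not_affecting")) return(FALSE)
      s <- as.numeric(cell)
      if (tool == "PROVEAN") s <= thr[["PROVEAN"]] else s >= thr[[tool]]
    }
    cons <- c(val("GERP"), val("PhyloP"), val("PhastCons"))
    dmg <- c(val("REVEL"), val("MetaLR"), val("MetaSVM"), val("CONDEL"),
             val("PROVEAN"), val("CADD_phred"))
    spl <- (isTRUE(val("dbscSNV_ADA")) && isTRUE(val("dbscSNV_RF"))) ||
      (isTRUE(val("MaxEntScan_class")) && isTRUE(val("HSF_class")))
    any(cons, na.rm = TRUE) || any(dmg, na.rm = TRUE) || spl
  }
  oracle_candidate <- function(row) {
    if (row$consequence %in% c("nonsense", "frameshift", "canonical_splice")) return(TRUE)
    if (row$consequence != "missense") return(FALSE)
    classes <- c("pathogenic", "likely_pathogenic", "vus", "conflicting")
    (row$clinvar_class %in% classes || row$acmg_class %in% classes) &&
      oracle_support(row)
  }
  for (seed in c(7, 8, 9)) {
    panel <- generate_variant_panel(60, decoy_mode = "straddling", seed = seed)
    panel <- apply_class_and_frequency_filters(panel)$kept
    got <- prioritize_candidates(panel)$candidates$variant_id
    want <- panel$variant_id[vapply(seq_len(nrow(panel)), function(i) {
      oracle_candidate(panel[i, ])
    }, logical(1))]
    expect_setequal(got, want)
  }
})

test_that("the cascade result does not depend on filter order", {
  panel <- generate_variant_panel(80, decoy_mode = "straddling", seed = 21)
  # cascade order
  cand1 <- filter_and_prioritize(panel)$candidates$variant_id
  # reversed: prioritization rules first, class/frequency after
  pre <- prioritize_candidates(panel)
  cand2 <- apply_class_and_frequency_filters(pre$candidates)$kept$variant_id
  expect_setequal(cand1, cand2)
})
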