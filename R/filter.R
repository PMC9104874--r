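#' Filtering and prioritization configuration
#'
#' Thresholds for the variant filtering cascade and the in-silico
#' prioritization rules. Defaults follow the published screening practice
#' for rare-variant discovery in a founder population:
#'
#' * genotype-call quality: minimum read depth 10, variant allele fraction
#'   within \[0.20, 0.80\] (bounds inclusive — the cascade *excludes*
#'   calls strictly below 0.20 or strictly above 0.80);
#' * class/frequency: silent and intronic variants removed; reference
#'   population MAF >= 0.01 removed; an absent (`NA`) MAF is kept, since
#'   absence from the reference database cannot justify excluding a novel
#'   founder variant;
#' * predictor thresholds (score scale, all inclusive `>=` unless noted):
#'   GERP 2.0, PhyloP 0.2, PhastCons 0.4, REVEL 0.4, MetaLR 0.4,
#'   MetaSVM 0.0, CONDEL 0.4, CADD (Phred) 20, dbscSNV ADA/RF 0.4.
#'   PROVEAN is directional: the tool's convention calls a variant
#'   damaging when its score is `<= -2.5`, which is the default
#'   (`provean_direction = "le"`); `"ge"` is available for sensitivity
#'   analyses against annotation stacks that report the opposite sign.
#'
#' @param maf_max maximum reference MAF retained (exclusive bound).
#' @param depth_min minimum read depth (inclusive).
#' @param vaf_min,vaf_max inclusive variant-allele-fraction window.
#' @param thresholds named numeric vector of predictor score thresholds.
#' @param provean_direction `"le"` (damaging iff score <= threshold,
#'   default) or `"ge"`.
#' @param aggregation_mode `"any_tool"` (default: one passing tool in any
#'   evidence category is support) or `"all_categories"` (every category
#'   with non-missing data must contribute a passing tool).
#' @param accepted_classes clinical classes under which a missense variant
#'   may be prioritized; "conflicting" is accepted as VUS-equivalent.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(maf_max = 0.01,
                          depth_min = 10L,
                          vaf_min = 0.20,
                          vaf_max = 0.80,
                          thresholds = c(GERP = 2.0, PhyloP = 0.2,
                                         PhastCons = 0.4, REVEL = 0.4,
                                         MetaLR = 0.4, MetaSVM = 0.0,
                                         CONDEL = 0.4, PROVEAN = -2.5,
                                         CADD_phred = 20,
                                         dbscSNV_ADA = 0.4, dbscSNV_RF = 0.4),
                          provean_direction = c("le", "ge"),
                          aggregation_mode = c("any_tool", "all_categories"),
                          accepted_classes = c("pathogenic", "likely_pathogenic",
                                               "vus", "conflicting")) {
  provean_direction <- match.arg(provean_direction)
  aggregation_mode <- match.arg(aggregation_mode)
  stopifnot(is_fraction(maf_max), is_count(depth_min),
            is_fraction(vaf_min), is_fraction(vaf_max), vaf_min < vaf_max,
            all(is.finite(thresholds)))
  structure(list(maf_max = maf_max, depth_min = as.integer(depth_min),
                 vaf_min = vaf_min, vaf_max = vaf_max,
                 thresholds = thresholds,
                 provean_direction = provean_direction,
                 aggregation_mode = aggregation_mode,
                 accepted_classes = accepted_classes),
            class = "filter_config")
}

#' Quality-filter genotype calls
#'
#' Keeps exactly the calls with `depth >= depth_min`, `vaf` inside the
#' inclusive window `[vaf_min, vaf_max]`, and a passing base quality.
#'
#' @param calls validated genotype-call table.
#' @param cfg a [filter_config()].
#' @return list with `kept` (the surviving calls) and `trace` (per-call
#'   verdicts with the first failing rule).
#' @export
apply_quality_filters <- function(calls, cfg = filter_config()) {
  validate_genotype_calls(calls)
  depth_ok <- calls$depth >= cfg$depth_min
  vaf_ok <- calls$vaf >= cfg$vaf_min & calls$vaf <= cfg$vaf_max
  qual_ok <- calls$base_quality_pass
  keep <- depth_ok & vaf_ok & qual_ok
  first_fail <- rep(NA_character_, nrow(calls))
  first_fail[!qual_ok] <- "base_quality"
  first_fail[!vaf_ok] <- "vaf_window"
  first_fail[!depth_ok] <- "low_coverage"
  trace <- data.frame(sample_id = calls$sample_id,
                      variant_id = calls$variant_id,
                      depth_pass = depth_ok, vaf_pass = vaf_ok,
                      base_quality_pass = qual_ok,
                      first_fail = first_fail,
                      status = ifelse(keep, "kept", "excluded"),
                      stringsAsFactors = FALSE)
  list(kept = calls[keep, , drop = FALSE], trace = trace)
}

#' Consequence-class and population-frequency filters
#'
#' Removes silent and intronic variants, and variants whose reference
#' population MAF is at or above `maf_max`. A missing MAF is retained:
#' the variant is treated as rare because it is absent from the reference
#' database.
#'
#' @param variants validated variant panel.
#' @param cfg a [filter_config()].
#' @return list with `kept` and `trace`.
#' @export
apply_class_and_frequency_filters <- function(variants, cfg = filter_config()) {
  validate_variant_panel(variants)
  class_ok <- !(variants$consequence %in% c("silent", "intronic"))
  freq_ok <- is.na(variants$maf_reference) | variants$maf_reference < cfg$maf_max
  keep <- class_ok & freq_ok
  first_fail <- rep(NA_character_, nrow(variants))
  first_fail[!freq_ok] <- "common_in_reference"
  first_fail[!class_ok] <- "silent_or_intronic"
  trace <- data.frame(variant_id = variants$variant_id,
                      class_pass = class_ok, frequency_pass = freq_ok,
                      first_fail = first_fail,
                      status = ifelse(keep, "kept", "excluded"),
                      stringsAsFactors = FALSE)
  list(kept = variants[keep, , drop = FALSE], trace = trace)
}

# verdict of a single predictor cell against its threshold.
# Returns TRUE (supports), FALSE (fails), or NA (missing / not applicable).
# Categorical labels take precedence over numeric scores, because curated
# panels are typically reported at label level.
predictor_verdict <- function(cell, tool, cfg) {
  if (is.na(cell)) return(NA)
  if (cell %in% predictor_labels()) {
    return(cell %in% c("conserved", "damaging", "pathogenic", "affecting_splicing"))
  }
  score <- suppressWarnings(as.numeric(cell))
  if (is.na(score)) return(NA)
  thr <- cfg$thresholds[[tool]]
  if (tool == "PROVEAN" && cfg$provean_direction == "le") {
    score <= thr
  } else {
    score >= thr
  }
}

#' Evaluate in-silico predictor support for one variant
#'
#' A variant is supported when at least one conservation tool meets its
#' threshold, or at least one protein-level/CADD tool calls it damaging,
#' or the splice consensus rule fires. The splice rule requires agreement
#' of two classifiers: both dbscSNV scores >= 0.4, or MaxEntScan *and*
#' HSF classifying the site as affecting splicing. Missing tools
#' contribute nothing. Under `aggregation_mode = "all_categories"` every
#' evidence category with non-missing data must contribute at least one
#' passing tool.
#'
#' @param variant one-row slice of a validated variant panel.
#' @param cfg a [filter_config()].
#' @return list with `supported` (logical) and `evidence` (character
#'   vector of satisfied tools; the consensus rule appears as
#'   `"splice_consensus"`).
#' @export
evaluate_insilico_support <- function(variant, cfg = filter_config()) {
  stopifnot(nrow(variant) == 1L)
  tools <- predictor_tools()
  verdict <- function(tool) predictor_verdict(variant[[tool]][1], tool, cfg)

  cons <- vapply(tools$conservation, verdict, logical(1))
  dmg <- vapply(tools$damaging, verdict, logical(1))
  ada <- verdict("dbscSNV_ADA"); rf <- verdict("dbscSNV_RF")
  mes <- verdict("MaxEntScan_class"); hsf <- verdict("HSF_class")
  splice_fires <- (isTRUE(ada) && isTRUE(rf)) || (isTRUE(mes) && isTRUE(hsf))

  evidence <- c(names(cons)[!is.na(cons) & cons],
                names(dmg)[!is.na(dmg) & dmg],
                if (splice_fires) "splice_consensus")
  category_pass <- c(conservation = any(cons, na.rm = TRUE),
                     damaging = any(dmg, na.rm = TRUE),
                     splice = splice_fires)
  if (cfg$aggregation_mode == "any_tool") {
    supported <- any(category_pass)
  } else {
    has_data <- c(conservation = any(!is.na(cons)),
                  damaging = any(!is.na(dmg)),
                  splice = any(!is.na(c(ada, rf, mes, hsf))))
    supported <- any(has_data) && all(category_pass[has_data])
  }
  list(supported = supported, evidence = evidence)
}

#' Prioritize candidate variants
#'
#' Applies the prioritization rule to a panel that already passed the
#' class/frequency filters: a variant is a candidate when it is
#' loss-of-function (nonsense, frameshift or canonical splice site), or
#' when it is missense, carries an accepted clinical classification
#' (pathogenic, likely pathogenic, VUS, or a conflicting record — which is
#' treated as VUS-equivalent) in ClinVar *or* under ACMG guidelines, and
#' has in-silico support per [evaluate_insilico_support()].
#'
#' @param variants validated variant panel (post class/frequency filters).
#' @param cfg a [filter_config()].
#' @return list with `candidates` (panel rows) and `trace` (one row per
#'   input variant: rule verdicts, first failing rule, final status, and
#'   the supporting evidence as a semicolon-joined string).
#' @export
prioritize_candidates <- function(variants, cfg = filter_config()) {
  validate_variant_panel(variants)
  n <- nrow(variants)
  is_lof <- variants$consequence %in% lof_consequences()
  is_missense <- variants$consequence == "missense"
  class_ok <- (variants$clinvar_class %in% cfg$accepted_classes) |
    (variants$acmg_class %in% cfg$accepted_classes)
  insilico <- lapply(seq_len(n), function(i) {
    evaluate_insilico_support(variants[i, , drop = FALSE], cfg)
  })
  insilico_ok <- vapply(insilico, `[[`, logical(1), "supported")
  evidence <- vapply(insilico, function(x) {
    paste(x$evidence, collapse = ";")
  }, character(1))

  candidate <- is_lof | (is_missense & class_ok & insilico_ok)
  first_fail <- rep(NA_character_, n)
  first_fail[!candidate] <- "no_insilico_support"
  first_fail[!candidate & is_missense & !class_ok] <- "clinical_class"
  first_fail[!candidate & !is_missense] <- "consequence_class"
  trace <- data.frame(variant_id = variants$variant_id,
                      lof = is_lof,
                      missense = is_missense,
                      clinical_class_pass = class_ok,
                      insilico_pass = insilico_ok,
                      evidence = evidence,
                      first_fail = first_fail,
                      status = ifelse(candidate, "candidate", "excluded"),
                      stringsAsFactors = FALSE)
  list(candidates = variants[candidate, , drop = FALSE], trace = trace)
}

#' Run the full variant filtering cascade
#'
#' Convenience wrapper: class/frequency filters followed by
#' prioritization. The final candidate set is order-independent (each rule
#' is a pure predicate on the variant), and every excluded variant carries
#' its first failing rule in the combined trace.
#'
#' @param variants validated variant panel.
#' @param cfg a [filter_config()].
#' @return list with `candidates` and `trace` (one row per input variant;
#'   `stage` records where a variant left the cascade).
#' @export
filter_and_prioritize <- function(variants, cfg = filter_config()) {
  step1 <- apply_class_and_frequency_filters(variants, cfg)
  step2 <- prioritize_candidates(step1$kept, cfg)
  t1 <- step1$trace[step1$trace$status == "excluded", c("variant_id", "first_fail")]
  t1$stage <- if (nrow(t1)) "class_frequency" else character(0)
  t2 <- step2$trace[, c("variant_id", "first_fail")]
  t2$stage <- if (nrow(t2)) "prioritization" else character(0)
  trace <- rbind(t1, t2)
  trace$status <- ifelse(trace$variant_id %in% step2$candidates$variant_id,
                         "candidate", "excluded")
  trace <- trace[match(intersect(variants$variant_id, trace$variant_id),
                       trace$variant_id), ]
  rownames(trace) <- NULL
  list(candidates = step2$candidates, trace = trace)
}
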