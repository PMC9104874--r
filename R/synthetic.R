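#' The five-variant founder candidate panel
#'
#' The packaged annotated panel of the two RAD51C and three RAD51D
#' candidate variants, with their published consequence classes, reference
#' population allele frequencies, clinical classifications and in-silico
#' predictor labels. Used as the default planted-variant templates of the
#' panel generator and as the fixture for the prioritization engine.
#'
#' @return validated variant panel data frame (5 rows).
#' @export
table1_variants <- function() {
  panel <- data.frame(
    variant_id = c("RAD51C:c.414G>C", "RAD51C:c.705G>T", "RAD51D:c.137C>G",
                   "RAD51D:c.620C>T", "RAD51D:c.694C>T"),
    gene = c("RAD51C", "RAD51C", "RAD51D", "RAD51D", "RAD51D"),
    genomic_change = c("g.56774063G>C", "g.56780690G>T", "g.33446137G>C",
                       "g.33430520G>A", "g.33430317G>A"),
    protein_change = c("p.Leu138Phe", "p.Lys235Asn", "p.Ser46Cys",
                       "p.Ser207Leu", "p.Arg232Ter"),
    consequence = c("missense", "missense", "missense", "missense", "nonsense"),
    maf_reference = c(0.00001, 0.00001, 0.0001, 0.0001, 0.00003),
    clinvar_class = c("pathogenic", "conflicting", "conflicting",
                      "conflicting", "pathogenic"),
    acmg_class = c("likely_pathogenic", "pathogenic", "vus", "vus", "pathogenic"),
    GERP = "conserved", PhyloP = "conserved", PhastCons = "conserved",
    REVEL = c("pathogenic", "benign", "pathogenic", "pathogenic", NA),
    MetaLR = c("tolerated", "tolerated", "tolerated", "damaging", NA),
    MetaSVM = c("tolerated", "tolerated", "tolerated", "damaging", NA),
    CONDEL = c("damaging", "tolerated", "damaging", "damaging", NA),
    PROVEAN = c("damaging", "tolerated", "damaging", "damaging", NA),
    CADD_phred = "damaging",
    dbscSNV_ADA = c(NA, "affecting_splicing", NA, NA, NA),
    dbscSNV_RF = c(NA, "affecting_splicing", NA, NA, NA),
    MaxEntScan_class = c(NA, "affecting_splicing", NA, NA, NA),
    HSF_class = c(NA, "affecting_splicing", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  validate_variant_panel(panel)
  panel
}

#' Cohort specification of the main carrier-frequency study
#'
#' The default cohort specification: three cancer study groups (44
#' ovarian-cancer families with 49 recruited participants, 56 breast/
#' ovarian syndrome families, 438 sporadic ovarian-cancer cases) and two
#' control groups (1025 sequencing-based, 8493 genotyping-based), the
#' published carrier counts per candidate variant, and nine
#' dual-membership cases recruited to two cancer groups. The
#' genotyping-based controls were assayed for only two of the variants;
#' the remaining pairs are absent from the count table (not assayed).
#'
#' @return list of class `cohort_spec` with `groups`, `carriers` (exact
#'   counts), `n_duplicates`.
#' @export
table2_cohort_spec <- function() {
  groups <- data.frame(
    name = c("oc_families", "hboc_families", "sporadic_oc",
             "seq_controls", "geno_controls"),
    role = c("case", "case", "case", "control", "control"),
    counting_unit = c("family", "family", "participant", "participant",
                      "participant"),
    n_units = c(44L, 56L, 438L, 1025L, 8493L),
    n_participants = c(49L, 56L, 438L, 1025L, 8493L),
    stringsAsFactors = FALSE
  )
  v <- table1_variants()$variant_id
  counts <- rbind(
    data.frame(group = "oc_families", variant_id = v,
               carriers = c(1L, 0L, 0L, 1L, 0L)),
    data.frame(group = "hboc_families", variant_id = v,
               carriers = c(0L, 0L, 0L, 0L, 0L)),
    data.frame(group = "sporadic_oc", variant_id = v,
               carriers = c(0L, 1L, 1L, 15L, 1L)),
    data.frame(group = "seq_controls", variant_id = v,
               carriers = c(1L, 0L, 0L, 1L, 0L)),
    data.frame(group = "geno_controls",
               variant_id = c("RAD51C:c.414G>C", "RAD51D:c.620C>T"),
               carriers = c(0L, 0L))
  )
  structure(list(groups = groups, carriers = counts, n_duplicates = 9L),
            class = "cohort_spec")
}

#' Cohort specification of the discovery phase
#'
#' The exome-sequenced discovery groups: 17 ovarian-cancer families (20
#' recruited familial cases) and 53 sporadic early-onset cases, with the
#' published per-variant carrier counts (counted in families for the
#' familial group, each carrier in a distinct family).
#'
#' @return list of class `cohort_spec`.
#' @export
phase1_cohort_spec <- function() {
  groups <- data.frame(
    name = c("oc_families_phase1", "sporadic_early_onset"),
    role = "case",
    counting_unit = c("family", "participant"),
    n_units = c(17L, 53L),
    n_participants = c(20L, 53L),
    stringsAsFactors = FALSE
  )
  v <- table1_variants()$variant_id
  counts <- rbind(
    data.frame(group = "oc_families_phase1", variant_id = v,
               carriers = c(1L, 0L, 0L, 2L, 0L)),
    data.frame(group = "sporadic_early_onset", variant_id = v,
               carriers = c(1L, 1L, 1L, 2L, 1L))
  )
  structure(list(groups = groups, carriers = counts, n_duplicates = 0L),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Builds a full participant roster for a [table2_cohort_spec()]-style
#' specification. Familial groups get `n_units` families with one index
#' case each; the surplus participants are assigned to random families.
#' Dual recruitment is emulated by merging `n_duplicates` membership
#' pairs drawn from two different case groups into single physical
#' participants, so the printed group sizes are preserved while the
#' unique-person count drops by `n_duplicates`.
#'
#' Carrier placement: when `spec$carriers` has a `carriers` column the
#' placement is an exact without-replacement assignment of counting units
#' (the resulting count table reproduces the specification with
#' probability 1, and no unit carries two variants); when it has a `prob`
#' column, counts are independent `Binomial(n_units, prob)` draws.
#'
#' @param spec a `cohort_spec` (see [table2_cohort_spec()]).
#' @param seed optional integer; when given, seeds the generator so the
#'   cohort is a pure function of `(spec, seed)`.
#' @return a `cohort`; the sampled carrier-unit assignments are attached
#'   as attribute `"carrier_assignments"`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  groups <- spec$groups
  parts <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    ids <- sprintf("%s_P%05d", g$name, seq_len(g$n_participants))
    if (g$counting_unit == "family") {
      fam <- sprintf("%s_F%04d", g$name, seq_len(g$n_units))
      extra <- g$n_participants - g$n_units
      fam_id <- c(fam, if (extra > 0) sample(fam, extra, replace = TRUE))
      is_index <- c(rep(TRUE, g$n_units), rep(FALSE, extra))
    } else {
      fam_id <- rep("", g$n_participants)
      is_index <- rep(TRUE, g$n_participants)
    }
    parts[[i]] <- data.frame(participant_id = ids, family_id = fam_id,
                             role = g$role, groups = g$name,
                             is_index = is_index, stringsAsFactors = FALSE)
  }
  participants <- do.call(rbind, parts)

  # merge duplicate memberships across distinct case groups
  n_dup <- spec$n_duplicates %||% 0L
  if (n_dup > 0L) {
    case_groups <- groups$name[groups$role == "case"]
    if (length(case_groups) < 2L) stop_input("generate_cohort: duplicates need >= 2 case groups")
    merged <- character(0)
    for (d in seq_len(n_dup)) {
      pair <- sample(case_groups, 2L)
      free1 <- which(participants$groups == pair[1] &
                       !(participants$participant_id %in% merged))
      free2 <- which(participants$groups == pair[2] &
                       !(participants$participant_id %in% merged))
      if (length(free1) == 0L || length(free2) == 0L) {
        stop_input("generate_cohort: infeasible duplicate specification")
      }
      keep <- if (length(free1) == 1L) free1 else sample(free1, 1L)
      drop <- if (length(free2) == 1L) free2 else sample(free2, 1L)
      participants$groups[keep] <- paste(participants$groups[keep],
                                         pair[2], sep = ";")
      merged <- c(merged, participants$participant_id[keep])
      participants <- participants[-drop, , drop = FALSE]
    }
  }
  rownames(participants) <- NULL

  # carrier placement
  has_counts <- "carriers" %in% names(spec$carriers)
  ctab <- spec$carriers
  if (!has_counts) {
    require_columns(ctab, c("group", "variant_id", "prob"), "carrier spec")
    nunits <- stats::setNames(groups$n_units, groups$name)
    ctab$carriers <- stats::rbinom(nrow(ctab), nunits[ctab$group], ctab$prob)
    ctab$prob <- NULL
  }
  assignments <- assign_carrier_units(ctab, groups, participants)
  x <- cohort(groups, participants, ctab[, c("group", "variant_id", "carriers")])
  attr(x, "carrier_assignments") <- assignments
  x
}

# sample which counting units carry each variant (no unit carries two)
assign_carrier_units <- function(ctab, groups, participants) {
  rows <- list()
  memberships <- strsplit(participants$groups, ";", fixed = TRUE)
  for (g in unique(ctab$group)) {
    grow <- groups[groups$name == g, ]
    in_g <- vapply(memberships, function(m) g %in% m, logical(1))
    if (grow$counting_unit == "family") {
      units <- setdiff(unique(participants$family_id[in_g]), c("", NA))
    } else {
      units <- participants$participant_id[in_g]
    }
    sub <- ctab[ctab$group == g & ctab$carriers > 0, , drop = FALSE]
    need <- sum(sub$carriers)
    if (need == 0L) next
    if (need > length(units)) {
      stop_input("generate_cohort: infeasible spec — ", need,
                 " carriers for ", length(units), " units in ", g)
    }
    chosen <- sample(units, need)
    at <- 0L
    for (r in seq_len(nrow(sub))) {
      take <- chosen[at + seq_len(sub$carriers[r])]
      at <- at + sub$carriers[r]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variant_id = sub$variant_id[r], unit = take,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group = character(0), variant_id = character(0),
                      unit = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic annotated variant panel
#'
#' Planted candidate variants (defaults: the five-variant founder panel,
#' which satisfy the prioritization rules by construction) are mixed with
#' `n_decoys` generated decoys. In `decoy_mode = "sub_threshold"` every
#' decoy predictor score is drawn strictly below its threshold and splice
#' classifiers read `not_affecting`, so the filtering cascade recovers
#' exactly the planted set; `"straddling"` draws scores across the
#' thresholds so that recovery degrades in a controlled way for
#' sensitivity analyses. Decoy reference MAFs are a mixture with mass
#' `maf_common_fraction` above the 0.01 frequency filter, a fraction
#' absent from the reference database (`NA`), and the rest rare.
#'
#' @param n_decoys number of decoy variants.
#' @param planted panel of planted variants (default [table1_variants()]).
#' @param decoy_mode `"sub_threshold"` or `"straddling"`.
#' @param maf_common_fraction mass of the decoy MAF mixture at or above
#'   0.01.
#' @param maf_missing_fraction mass of the decoy MAF mixture absent from
#'   the reference database.
#' @param seed optional integer seed.
#' @return validated variant panel (planted rows first).
#' @export
generate_variant_panel <- function(n_decoys, planted = table1_variants(),
                                   decoy_mode = c("sub_threshold", "straddling"),
                                   maf_common_fraction = 0.3,
                                   maf_missing_fraction = 0.2,
                                   seed = NULL) {
  decoy_mode <- match.arg(decoy_mode)
  stopifnot(maf_common_fraction + maf_missing_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (n_decoys == 0L) return(planted)

  runif_below <- function(n, lo, hi) stats::runif(n, lo, hi - 1e-6)
  n <- n_decoys
  gene <- sample(c("RAD51C", "RAD51D"), n, replace = TRUE)
  pos <- sample(100:99999, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  consequence <- sample(c("missense", "silent", "intronic"), n,
                        replace = TRUE, prob = c(0.5, 0.25, 0.25))
  u <- stats::runif(n)
  maf <- ifelse(u < maf_common_fraction, stats::runif(n, 0.01, 0.5),
                ifelse(u < maf_common_fraction + maf_missing_fraction,
                       NA_real_, stats::runif(n, 0, 0.005)))
  score <- function(lo_sub, hi_sub, lo_str, hi_str) {
    if (decoy_mode == "sub_threshold") runif_below(n, lo_sub, hi_sub)
    else stats::runif(n, lo_str, hi_str)
  }
  decoys <- data.frame(
    variant_id = sprintf("%s:c.%d%s>%s", gene, pos, ref, alt),
    gene = gene,
    genomic_change = sprintf("g.%d%s>%s", 33400000L + pos, ref, alt),
    protein_change = NA_character_,
    consequence = consequence,
    maf_reference = maf,
    clinvar_class = sample(c("benign", "likely_benign", "vus", "not_reported"),
                           n, replace = TRUE),
    acmg_class = sample(c("benign", "likely_benign", "vus"), n, replace = TRUE),
    GERP = as.character(score(-12.3, 2.0, -12.3, 6.2)),
    PhyloP = as.character(score(-5, 0.2, -5, 3)),
    PhastCons = as.character(score(0, 0.4, 0, 1)),
    REVEL = as.character(score(0, 0.4, 0, 1)),
    MetaLR = as.character(score(0, 0.4, 0, 1)),
    MetaSVM = as.character(score(-2, 0.0, -2, 2)),
    CONDEL = as.character(score(0, 0.4, 0, 1)),
    PROVEAN = as.character(score(-2.4, 6, -8, 6)),  # damaging iff <= -2.5
    CADD_phred = as.character(score(0, 20, 0, 40)),
    dbscSNV_ADA = as.character(score(0, 0.4, 0, 1)),
    dbscSNV_RF = as.character(score(0, 0.4, 0, 1)),
    MaxEntScan_class = "not_affecting",
    HSF_class = "not_affecting",
    stringsAsFactors = FALSE
  )
  # id collisions with planted or among decoys are vanishingly rare but fatal
  decoys <- decoys[!duplicated(decoys$variant_id) &
                     !(decoys$variant_id %in% planted$variant_id), , drop = FALSE]
  panel <- rbind(planted, decoys)
  rownames(panel) <- NULL
  validate_variant_panel(panel)
  panel
}

#' Generate synthetic tumour/normal LOH observations
#'
#' Tumour variant allele fractions are binomial draws at the given read
#' depth around [expected_variant_fraction()] for each observation's
#' purity and somatic state; normal fractions are binomial around the
#' germline-heterozygous 0.5.
#'
#' @param purities tumour-cell fractions in \[0, 1\].
#' @param states per-observation somatic state, `"wild_type_loss"` or
#'   `"retained_het"` (recycled).
#' @param depth sequencing depth for both tissues.
#' @param seed optional integer seed.
#' @return LOH observation data frame (see [read_loh_table()]) with the
#'   generating `purity` and `true_state` appended.
#' @export
generate_loh_observations <- function(purities, states = "wild_type_loss",
                                      depth = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(purities < 0 | purities > 1)) stop_input("purities must be in [0, 1]")
  n <- length(purities)
  states <- rep_len(states, n)
  ev <- vapply(seq_len(n), function(i) {
    expected_variant_fraction(purities[i], states[i])
  }, numeric(1))
  data.frame(
    carrier_id = sprintf("SIM%04d", seq_len(n)),
    variant_id = "RAD51D:c.620C>T",
    tissue = "ovary",
    preservation = "fresh_frozen",
    normal_vaf = stats::rbinom(n, depth, 0.5) / depth,
    tumour_vaf = stats::rbinom(n, depth, ev) / depth,
    tumour_depth = as.integer(depth),
    purity = purities,
    true_state = states,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic clinical table
#'
#' One arm per row of `arms`: ages at diagnosis are normal draws truncated
#' to \[25, 90\] years (resampled until inside the range); survival months
#' are gamma draws (shape 2) matched to the arm's mean survival.
#'
#' @param arms data frame with columns `variant_id`, `n`, `age_mean`,
#'   `age_sd`, `survival_mean`.
#' @param seed optional integer seed.
#' @return clinical table (see [read_clinical_table()]).
#' @export
generate_clinical_table <- function(arms, seed = NULL) {
  require_columns(arms, c("variant_id", "n", "age_mean", "age_sd",
                          "survival_mean"), "arms")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    ages <- numeric(0)
    while (length(ages) < a$n) {
      draw <- stats::rnorm(a$n, a$age_mean, a$age_sd)
      ages <- c(ages, draw[draw >= 25 & draw <= 90])
    }
    ages <- round(ages[seq_len(a$n)])
    surv <- round(stats::rgamma(a$n, shape = 2, scale = a$survival_mean / 2))
    data.frame(
      carrier_id = sprintf("%s_C%03d", gsub("[^A-Za-z0-9]", "", a$variant_id),
                           seq_len(a$n)),
      variant_id = a$variant_id,
      age_at_diagnosis = ages,
      survival_months = surv,
      vital_status = sample(c("deceased_oc", "alive", "other"), a$n,
                            replace = TRUE, prob = c(0.5, 0.4, 0.1)),
      histopathology = sample(c("HGSC", "endometrioid", "serous_unknown_grade"),
                              a$n, replace = TRUE, prob = c(0.9, 0.05, 0.05)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
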