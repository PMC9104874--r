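#' Domain tables and their validators
#'
#' The package represents its domain objects as plain data frames with a
#' fixed column contract, validated on construction and on file input:
#'
#' * **variant panel** — one row per annotated germline variant: identity
#'   (`variant_id` = gene + HGVS c. notation, `gene`, `genomic_change`,
#'   `protein_change`), `consequence` class, reference-population minor
#'   allele frequency `maf_reference` (`NA` = absent from the reference
#'   database, which is *not* the same as 0), in-silico predictor columns
#'   (see [predictor_tools()]) and `clinvar_class` / `acmg_class`.
#' * **genotype calls** — one row per sample x variant observation with
#'   read `depth`, variant allele fraction `vaf` and `base_quality_pass`.
#' * **cohort** — study groups, participants and a carrier-count table,
#'   see [cohort()].
#'
#' Missing values are carried as `NA` throughout and survive serialization;
#' they are never coerced to zero.
#'
#' @name carrierscan-types
NULL

consequence_levels <- function() {
  c("missense", "nonsense", "frameshift", "canonical_splice",
    "silent", "intronic", "other")
}

lof_consequences <- function() c("nonsense", "frameshift", "canonical_splice")

clinical_class_levels <- function() {
  c("pathogenic", "likely_pathogenic", "vus", "conflicting",
    "likely_benign", "benign", "not_reported")
}

#' In-silico predictor panel layout
#'
#' Returns the predictor tools understood by the prioritization engine,
#' grouped by the kind of evidence they contribute. Conservation and
#' protein/CADD tools may carry a numeric score, a categorical label, or
#' both (labels take precedence); the splice consensus classifiers
#' (`MaxEntScan_class`, `HSF_class`) are categorical only.
#'
#' @return named list with character vectors `conservation`, `damaging`,
#'   `splice_score`, `splice_class`.
#' @export
predictor_tools <- function() {
  list(
    conservation = c("GERP", "PhyloP", "PhastCons"),
    damaging     = c("REVEL", "MetaLR", "MetaSVM", "CONDEL", "PROVEAN",
                     "CADD_phred"),
    splice_score = c("dbscSNV_ADA", "dbscSNV_RF"),
    splice_class = c("MaxEntScan_class", "HSF_class")
  )
}

predictor_columns <- function() unlist(predictor_tools(), use.names = FALSE)

predictor_labels <- function() {
  c("conserved", "not_conserved", "damaging", "tolerated",
    "pathogenic", "benign", "affecting_splicing", "not_affecting")
}

variant_panel_columns <- function() {
  c("variant_id", "gene", "genomic_change", "protein_change", "consequence",
    "maf_reference", "clinvar_class", "acmg_class", predictor_columns())
}

#' Validate a variant panel
#'
#' Checks the column contract described in [carrierscan-types]: unique
#' `variant_id`, recognised `consequence` and clinical classes,
#' `maf_reference` in \[0, 1\] when present, and predictor cells that are
#' numeric scores, recognised labels, or `NA`.
#'
#' @param panel data frame of annotated variants.
#' @return the panel, invisibly, with predictor columns as character.
#' @export
validate_variant_panel <- function(panel) {
  require_columns(panel, variant_panel_columns(), "variant panel")
  if (anyDuplicated(panel$variant_id)) {
    stop_input("variant panel: duplicated variant_id")
  }
  bad <- setdiff(unique(panel$consequence), consequence_levels())
  if (length(bad) > 0L) {
    stop_input("variant panel: unknown consequence: ", paste(bad, collapse = ", "))
  }
  for (cl in c("clinvar_class", "acmg_class")) {
    bad <- setdiff(unique(panel[[cl]][!is.na(panel[[cl]])]), clinical_class_levels())
    if (length(bad) > 0L) {
      stop_input("variant panel: unknown ", cl, ": ", paste(bad, collapse = ", "))
    }
  }
  maf <- panel$maf_reference
  if (!is.numeric(maf)) stop_input("variant panel: maf_reference must be numeric (NA for absent)")
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop_input("variant panel: maf_reference outside [0, 1]")
  }
  for (tool in predictor_columns()) {
    panel[[tool]] <- as.character(panel[[tool]])
    cell <- panel[[tool]]
    known <- is.na(cell) | cell %in% predictor_labels() |
      !is.na(suppressWarnings(as.numeric(cell)))
    if (!all(known)) {
      stop_input("variant panel: unparseable ", tool, " entry: ",
                 paste(unique(cell[!known]), collapse = ", "))
    }
  }
  for (cl in predictor_tools()$splice_class) {
    num <- !is.na(suppressWarnings(as.numeric(panel[[cl]])))
    if (any(num)) stop_input("variant panel: ", cl, " is categorical only")
  }
  invisible(panel)
}

#' Validate a genotype-call table
#'
#' @param calls data frame with columns `sample_id`, `variant_id`, `depth`
#'   (non-negative integer), `vaf` in \[0, 1\], `base_quality_pass` (logical).
#' @return the calls, invisibly.
#' @export
validate_genotype_calls <- function(calls) {
  require_columns(calls,
                  c("sample_id", "variant_id", "depth", "vaf", "base_quality_pass"),
                  "genotype calls")
  if (any(calls$depth < 0 | calls$depth != floor(calls$depth))) {
    stop_input("genotype calls: depth must be a non-negative integer")
  }
  if (any(calls$vaf < 0 | calls$vaf > 1, na.rm = TRUE)) {
    stop_input("genotype calls: vaf outside [0, 1]")
  }
  if (!is.logical(calls$base_quality_pass)) {
    stop_input("genotype calls: base_quality_pass must be logical")
  }
  invisible(calls)
}

#' Construct and validate a cohort
#'
#' A cohort bundles the recruitment structure of a case-control study:
#'
#' * `groups`: one row per study group with `name`, `role`
#'   (`"case"`/`"control"`), `counting_unit` (`"participant"` or `"family"`
#'   — familial groups are counted by family so that a carrier family
#'   contributes once to the numerator and the denominator), `n_units` and
#'   `n_participants`.
#' * `participants`: one row per physical person with `participant_id`,
#'   `family_id` (empty for non-familial recruits), `role`, `is_index`, and
#'   `groups` — a semicolon-separated membership list; more than one entry
#'   encodes the same person recruited to two study groups.
#' * `carriers`: long table `(group, variant_id, carriers)` of carrier
#'   counts per group in the group's counting unit. Pairs absent from the
#'   table were not assayed in that group (distinct from an observed 0).
#'
#' @param groups,participants,carriers data frames as described above.
#' @return an object of class `cohort` (a named list of the three tables).
#' @export
cohort <- function(groups, participants, carriers) {
  require_columns(groups,
                  c("name", "role", "counting_unit", "n_units", "n_participants"),
                  "groups")
  require_columns(participants,
                  c("participant_id", "family_id", "role", "groups", "is_index"),
                  "participants")
  require_columns(carriers, c("group", "variant_id", "carriers"), "carriers")

  if (anyDuplicated(groups$name)) stop_input("groups: duplicated group name")
  if (!all(groups$role %in% c("case", "control"))) {
    stop_input("groups: role must be 'case' or 'control'")
  }
  if (!all(groups$counting_unit %in% c("participant", "family"))) {
    stop_input("groups: counting_unit must be 'participant' or 'family'")
  }
  if (any(groups$n_units <= 0 | groups$n_participants <= 0)) {
    stop_input("groups: n_units and n_participants must be positive")
  }
  if (any(groups$n_units > groups$n_participants)) {
    stop_input("groups: n_units exceeds n_participants")
  }
  if (anyDuplicated(participants$participant_id)) {
    stop_input("participants: duplicated participant_id")
  }
  memberships <- strsplit(participants$groups, ";", fixed = TRUE)
  if (any(lengths(memberships) < 1L)) {
    stop_input("participants: every participant needs at least one group membership")
  }
  unknown <- setdiff(unique(unlist(memberships)), groups$name)
  if (length(unknown) > 0L) {
    stop_input("participants: membership in unknown group(s): ",
               paste(unknown, collapse = ", "))
  }
  # group sizes must match membership counts
  tab <- table(factor(unlist(memberships), levels = groups$name))
  size_ok <- as.integer(tab[groups$name]) == groups$n_participants
  if (!all(size_ok)) {
    stop_input("cohort: participant memberships do not match n_participants for: ",
               paste(groups$name[!size_ok], collapse = ", "))
  }
  # role consistency across memberships: participant role must equal the
  # role of every group it belongs to
  grole <- stats::setNames(groups$role, groups$name)
  role_ok <- mapply(function(ms, r) all(grole[ms] == r),
                    memberships, participants$role)
  if (!all(role_ok)) {
    stop_input("participants: role inconsistent with group role for: ",
               paste(participants$participant_id[!role_ok], collapse = ", "))
  }
  validate_carrier_table(carriers, groups,
                         n_participants = length(memberships))
  structure(list(groups = groups, participants = participants,
                 carriers = carriers),
            class = "cohort")
}

#' Validate a carrier-count table against group denominators
#'
#' @param carriers long table `(group, variant_id, carriers)`.
#' @param groups group table (see [cohort()]).
#' @param n_participants optional: if 0, any non-zero carrier count is
#'   rejected (carriers cannot exist without participants).
#' @return the carrier table, invisibly.
#' @export
validate_carrier_table <- function(carriers, groups, n_participants = NULL) {
  require_columns(carriers, c("group", "variant_id", "carriers"), "carriers")
  if (any(carriers$carriers < 0 | carriers$carriers != floor(carriers$carriers))) {
    stop_input("carriers: counts must be non-negative integers")
  }
  unknown <- setdiff(unique(carriers$group), groups$name)
  if (length(unknown) > 0L) {
    stop_input("carriers: counts for unknown group(s): ",
               paste(unknown, collapse = ", "))
  }
  nunits <- stats::setNames(groups$n_units, groups$name)
  over <- carriers$carriers > nunits[carriers$group]
  if (any(over)) {
    stop_input("carriers: carrier count exceeds group denominator for ",
               paste(unique(carriers$group[over]), collapse = ", "))
  }
  if (!is.null(n_participants) && n_participants == 0 &&
      any(carriers$carriers > 0)) {
    stop_input("carriers: non-zero carrier counts with no participants")
  }
  invisible(carriers)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$groups), "study groups,",
      nrow(x$participants), "participants,",
      nrow(x$carriers), "carrier-count cells\n")
  cat(sprintf("  %-22s %-8s %-12s %6s %6s\n",
              "group", "role", "unit", "units", "n"))
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %-22s %-8s %-12s %6d %6d\n", g$name, g$role,
                g$counting_unit, g$n_units, g$n_participants))
  }
  invisible(x)
}

# carrier count for (group, variant); NA when the pair was not assayed
carrier_count <- function(carriers, group, variant_id) {
  hit <- carriers$group == group & carriers$variant_id == variant_id
  if (!any(hit)) return(NA_integer_)
  sum(carriers$carriers[hit])
}
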