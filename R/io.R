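#' Read an annotated variant panel
#'
#' Reads a variant panel either from a TSV file with the declared header
#' (see [carrierscan-types]) or from a VCF whose INFO field carries the
#' annotations, with a configurable INFO-key map. Missing values (`NA`,
#' `"NA"`, `"-"`, empty cells, absent INFO keys) are preserved as `NA` and
#' never coerced to 0.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"vcf_info"`.
#' @param info_map named character vector mapping panel columns to VCF INFO
#'   keys; defaults to [default_info_map()]. Used only for `"vcf_info"`.
#' @return validated variant panel data frame.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_info"),
                               info_map = default_info_map()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("variant table not found: ", path)
  panel <- switch(dialect,
                  tsv = read_variant_tsv(path),
                  vcf_info = read_variant_vcf(path, info_map))
  validate_variant_panel(panel)
  panel
}

read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", "-", ""), check.names = FALSE,
                          colClasses = "character")
  require_columns(df, variant_panel_columns(), basename(path))
  maf <- suppressWarnings(as.numeric(df$maf_reference))
  bad <- !is.na(df$maf_reference) & is.na(maf)
  if (any(bad)) {
    stop_input(sprintf("%s: unparseable maf_reference '%s' at data row %d",
                       basename(path), df$maf_reference[which(bad)[1]],
                       which(bad)[1]))
  }
  df$maf_reference <- maf
  df[, variant_panel_columns()]
}

#' Default VCF INFO key map for variant panels
#'
#' Annotation stacks differ in how they name INFO keys, so the VCF reader
#' takes the mapping as configuration. The default uses the panel column
#' names verbatim (upper-cased identity for the non-predictor fields).
#'
#' @return named character vector: panel column -> INFO key.
#' @export
default_info_map <- function() {
  cols <- c("gene", "protein_change", "consequence", "maf_reference",
            "clinvar_class", "acmg_class", predictor_columns())
  stats::setNames(c("GENE", "PCHANGE", "CSQCLASS", "MAF_REF",
                    "CLINVAR", "ACMG", predictor_columns()),
                  cols)
}

read_variant_vcf <- function(path, info_map) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  get_info <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else as.character(v)
  }
  gene <- get_info(info_map[["gene"]])
  coding <- get_info("HGVSC")
  panel <- data.frame(
    variant_id = ifelse(is.na(coding) | is.na(gene), fix$ID,
                        paste0(gene, ":", coding)),
    gene = gene,
    genomic_change = paste0("g.", fix$POS, fix$REF, ">", fix$ALT),
    protein_change = get_info(info_map[["protein_change"]]),
    consequence = get_info(info_map[["consequence"]]),
    maf_reference = suppressWarnings(as.numeric(get_info(info_map[["maf_reference"]]))),
    clinvar_class = get_info(info_map[["clinvar_class"]]),
    acmg_class = get_info(info_map[["acmg_class"]]),
    stringsAsFactors = FALSE
  )
  for (tool in predictor_columns()) {
    panel[[tool]] <- get_info(info_map[[tool]])
  }
  panel
}

#' Write a variant panel to TSV
#'
#' Deterministic serialization: the same panel always produces a
#' byte-identical file, and `read_variant_table()` on the result restores
#' the panel (missing values round-trip as `NA`).
#'
#' @param panel validated variant panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(panel, path) {
  validate_variant_panel(panel)
  write_tsv(panel[, variant_panel_columns()], path)
}

#' Read a cohort from its three tables
#'
#' Expects `groups.tsv`, `participants.tsv` and `carriers.tsv` under `dir`
#' (names overridable). All [cohort()] invariants are enforced; a carrier
#' count exceeding its group denominator is a validation error.
#'
#' @param dir directory holding the three files.
#' @param groups_file,participants_file,carriers_file file names within `dir`.
#' @return a `cohort` object.
#' @export
read_cohort <- function(dir, groups_file = "groups.tsv",
                        participants_file = "participants.tsv",
                        carriers_file = "carriers.tsv") {
  paths <- file.path(dir, c(groups_file, participants_file, carriers_file))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop_input("cohort files not found: ", paste(missing, collapse = ", "))
  }
  groups <- utils::read.delim(paths[1], stringsAsFactors = FALSE)
  participants <- utils::read.delim(paths[2], stringsAsFactors = FALSE,
                                    na.strings = character(0))
  participants$is_index <- as.logical(participants$is_index)
  carriers <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  cohort(groups, participants, carriers)
}

#' Write a cohort to a directory
#'
#' Inverse of [read_cohort()]; rerunning on the same cohort yields
#' byte-identical files.
#'
#' @param x a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(x$groups, file.path(dir, "groups.tsv"))
  write_tsv(x$participants, file.path(dir, "participants.tsv"))
  write_tsv(x$carriers, file.path(dir, "carriers.tsv"))
  invisible(dir)
}

#' Write a stage result to disk
#'
#' Data frames are written as TSV, everything else as JSON. Serialization
#' is deterministic: rerunning on identical input produces a byte-identical
#' file (no timestamps, fixed column order, full double precision).
#'
#' @param results data frame or list.
#' @param path output path; the extension does not alter the format chosen.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_input("unwritable path (no such directory): ", dir)
  if (is.data.frame(results)) {
    write_tsv(results, path)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read tumour/normal allele-fraction observations
#'
#' @param path TSV with columns `carrier_id`, `variant_id`, `tissue`,
#'   `preservation` (`fresh_frozen`/`FFPE`), `normal_vaf`, `tumour_vaf`,
#'   `tumour_depth`.
#' @return validated data frame.
#' @export
read_loh_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("carrier_id", "variant_id", "tissue", "preservation",
                        "normal_vaf", "tumour_vaf", "tumour_depth"),
                  basename(path))
  if (any(df$normal_vaf < 0 | df$normal_vaf > 1 |
          df$tumour_vaf < 0 | df$tumour_vaf > 1, na.rm = TRUE)) {
    stop_input(basename(path), ": allele fractions outside [0, 1]")
  }
  if (!all(df$preservation %in% c("fresh_frozen", "FFPE"))) {
    stop_input(basename(path), ": preservation must be fresh_frozen or FFPE")
  }
  df
}

#' Read a clinical table
#'
#' @param path TSV with columns `carrier_id`, `variant_id`,
#'   `age_at_diagnosis` (years), `survival_months` (`NA` if unknown),
#'   `vital_status`, `histopathology`.
#' @return validated data frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("carrier_id", "variant_id", "age_at_diagnosis",
                        "survival_months", "vital_status", "histopathology"),
                  basename(path))
  if (any(df$age_at_diagnosis <= 0, na.rm = TRUE)) {
    stop_input(basename(path), ": ages must be positive")
  }
  if (any(df$survival_months < 0, na.rm = TRUE)) {
    stop_input(basename(path), ": survival months must be non-negative")
  }
  df
}
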