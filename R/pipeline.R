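#' Assemble and validate a pipeline run configuration
#'
#' A run configuration names the input files, the output directory, the
#' global seed, and stage options. It can be built in code or loaded from
#' a YAML file with the same field names. Referenced input files must
#' exist at validation time.
#'
#' @param variants path to the annotated variant panel (TSV).
#' @param cohort_dir directory with `groups.tsv`, `participants.tsv`,
#'   `carriers.tsv` (optional: enrichment/permutation stages are skipped
#'   when absent).
#' @param calls optional genotype-call TSV for the quality-filter stage.
#' @param loh optional LOH observation TSV.
#' @param clinical optional clinical TSV.
#' @param out_dir output directory, created if needed.
#' @param seed global integer seed recorded in every output.
#' @param pairs data frame of case/control group pairs for the
#'   enrichment stage (default: each case group vs `seq_controls`).
#' @param filter a [filter_config()].
#' @param n_permutations permutations for the permutation stage.
#' @param tests permutation test set; default [default_test_set()] built
#'   from the panel's variants.
#' @param loh_thresholds a [loh_thresholds()].
#' @return list of class `run_config`.
#' @export
run_config <- function(variants, cohort_dir = NULL, calls = NULL,
                       loh = NULL, clinical = NULL,
                       out_dir, seed,
                       pairs = NULL,
                       filter = filter_config(),
                       n_permutations = 5000L,
                       tests = NULL,
                       loh_thresholds = carrierscan::loh_thresholds()) {
  for (f in c(variants, calls, loh, clinical)) {
    if (!is.null(f) && !file.exists(f)) stop_input("run_config: input not found: ", f)
  }
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir)) {
    stop_input("run_config: cohort directory not found: ", cohort_dir)
  }
  stopifnot(is_count(seed) || (is.numeric(seed) && seed == floor(seed)))
  structure(list(variants = variants, cohort_dir = cohort_dir, calls = calls,
                 loh = loh, clinical = clinical, out_dir = out_dir,
                 seed = as.integer(seed), pairs = pairs, filter = filter,
                 n_permutations = as.integer(n_permutations), tests = tests,
                 loh_thresholds = loh_thresholds),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments
#'   (file paths are resolved relative to the YAML's directory).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|~|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  run_config(variants = rel(y$variants), cohort_dir = rel(y$cohort_dir),
             calls = rel(y$calls), loh = rel(y$loh),
             clinical = rel(y$clinical), out_dir = rel(y$out_dir),
             seed = y$seed,
             pairs = if (!is.null(y$pairs)) do.call(rbind, lapply(y$pairs, as.data.frame)),
             n_permutations = y$n_permutations %||% 5000L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_input(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' filter -> prioritize -> enrichment -> permutation -> LOH -> clinical,
#' writing one artefact per stage into `config$out_dir`:
#' `candidates.tsv` and `filter_trace.tsv`, `enrichment.tsv`,
#' `permutation.json`, `loh_calls.tsv`, `clinical_summary.tsv`, and a
#' `manifest.json` recording the seed, a hash of the configuration and
#' the MD5 of every artefact. All randomness funnels through
#' `config$seed`; rerunning with an identical configuration produces
#' byte-identical artefacts. A failing stage aborts with the stage name
#' in the error.
#'
#' @param config a [run_config()].
#' @return list with the in-memory stage results and the manifest,
#'   invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(config$seed)
  results <- list()

  variants <- stage("read_variants", read_variant_table(config$variants))

  if (!is.null(config$calls)) {
    calls <- stage("read_calls", {
      df <- utils::read.delim(config$calls, stringsAsFactors = FALSE)
      df$base_quality_pass <- as.logical(df$base_quality_pass)
      validate_genotype_calls(df)
      df
    })
    qf <- stage("quality_filter", apply_quality_filters(calls, config$filter))
    write_report(qf$trace, file.path(out, "call_quality_trace.tsv"))
    results$quality <- qf
  }

  pr <- stage("prioritize", filter_and_prioritize(variants, config$filter))
  write_report(pr$candidates, file.path(out, "candidates.tsv"))
  write_report(pr$trace, file.path(out, "filter_trace.tsv"))
  results$candidates <- pr$candidates

  if (!is.null(config$cohort_dir)) {
    cohort <- stage("read_cohort", read_cohort(config$cohort_dir))
    pairs <- config$pairs
    if (is.null(pairs)) {
      cases <- cohort$groups$name[cohort$groups$role == "case"]
      ctrl <- if ("seq_controls" %in% cohort$groups$name) "seq_controls" else
        cohort$groups$name[cohort$groups$role == "control"][1]
      pairs <- data.frame(case_group = cases, control_group = ctrl,
                          stringsAsFactors = FALSE)
    }
    enr <- stage("enrichment", pairwise_case_control_tests(cohort, pairs))
    write_report(enr, file.path(out, "enrichment.tsv"))
    results$enrichment <- enr

    tests <- config$tests %||%
      default_test_set(variants = unique(cohort$carriers$variant_id))
    perm <- stage("permutation", run_permutation_study(
      cohort, permutation_config(tests, n_permutations = config$n_permutations,
                                 seed = config$seed)))
    write_report(list(tests = perm$tests,
                      fwer_estimate = perm$fwer_estimate,
                      fwer_se = perm$fwer_se,
                      joint_significance = perm$joint_significance,
                      joint_se = perm$joint_se,
                      n_permutations = perm$n_permutations,
                      seed = perm$seed, alpha = perm$alpha,
                      allocation_unit = perm$allocation_unit),
                 file.path(out, "permutation.json"))
    results$permutation <- perm
  }

  if (!is.null(config$loh)) {
    loh <- stage("loh", call_loh(read_loh_table(config$loh),
                                 config$loh_thresholds))
    write_report(loh, file.path(out, "loh_calls.tsv"))
    results$loh <- loh
  }

  if (!is.null(config$clinical)) {
    clin <- stage("clinical", clinical_summary_table(
      read_clinical_table(config$clinical)))
    write_report(clin, file.path(out, "clinical_summary.tsv"))
    results$clinical <- clin
  }

  manifest <- build_manifest(config, out)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

build_manifest <- function(config, out) {
  cfg_plain <- unclass(config)
  cfg_plain$filter <- unclass(cfg_plain$filter)
  cfg_plain$loh_thresholds <- unclass(cfg_plain$loh_thresholds)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  artefacts <- sort(setdiff(list.files(out), "manifest.json"))
  list(seed = config$seed,
       config_md5 = cfg_hash,
       artefacts = as.list(stats::setNames(
         unname(tools::md5sum(file.path(out, artefacts))), artefacts)))
}
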