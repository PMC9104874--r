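#!/usr/bin/env Rscript
# Stage 2 — variant filtering and prioritization.
#
# Runs the filtering cascade (consequence class, reference-population
# frequency, in-silico predictor support, clinical classification) over
# the annotated panel and reports the candidate set with its audit trail,
# plus the discovery-phase carrier summaries.

suppressPackageStartupMessages(library(carrierscan))
dir.create("results", showWarnings = FALSE)

panel <- read_variant_table("results/inputs/variant_panel.tsv")
res <- filter_and_prioritize(panel)
write_report(res$candidates, "results/candidates.tsv")
write_report(res$trace, "results/filter_trace.tsv")

cat(sprintf("%d of %d variants prioritized as candidates:\n",
            nrow(res$candidates), nrow(panel)))
print(res$candidates[, c("variant_id", "consequence", "clinvar_class", "acmg_class")],
      row.names = FALSE)

phase1 <- read_cohort("results/inputs/cohort_phase1")
s <- carrier_summary(phase1)
write_report(s, "results/phase1_carrier_summary.tsv")
cat("\nDiscovery-phase carrier frequencies (any candidate variant):\n")
print(s[, c("group", "label")], row.names = FALSE)
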