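#!/usr/bin/env Rscript
# Stage 6 — clinico-pathological summaries.
#
# Descriptive statistics of age at diagnosis and survival for the two
# synthetic carrier arms (the high-frequency RAD51D founder variant and
# the comparison BRCA1 founder allele), age-cutoff proportions, and the
# unpaired pooled-variance t-tests between the arms.

suppressPackageStartupMessages(library(carrierscan))

clin <- read_clinical_table("results/inputs/clinical.tsv")
tab <- clinical_summary_table(clin)
write_report(tab, "results/clinical_summary.tsv")
print(tab, row.names = FALSE, digits = 3)

arms <- split(clin, clin$variant_id)
stopifnot(length(arms) == 2L)
age <- unpaired_t_test(arms[[2]]$age_at_diagnosis, arms[[1]]$age_at_diagnosis)
surv <- unpaired_t_test(arms[[2]]$survival_months, arms[[1]]$survival_months)
cmp <- data.frame(measure = c("age_at_diagnosis", "survival_months"),
                  mean_a = c(age$mean_a, surv$mean_a),
                  mean_b = c(age$mean_b, surv$mean_b),
                  t = c(age$t, surv$t),
                  p_two_sided = c(age$p_two_sided, surv$p_two_sided),
                  ci_low = c(age$ci_low, surv$ci_low),
                  ci_high = c(age$ci_high, surv$ci_high))
write_report(cmp, "results/clinical_comparison.tsv")
cat(sprintf("\n%s vs %s:\n", names(arms)[2], names(arms)[1]))
print(cmp, row.names = FALSE, digits = 3)
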