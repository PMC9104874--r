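#' Descriptive summary of a clinical measurement
#'
#' @param values non-empty numeric vector (`NA`s dropped).
#' @return list with `n`, `mean`, `median`, `min`, `max` and `sd` (the
#'   sample standard deviation, `n - 1` denominator; `NA` when `n < 2`).
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_input("summarize_values: empty input")
  list(n = length(values),
       mean = mean(values),
       median = stats::median(values),
       min = min(values),
       max = max(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

#' Proportion of values strictly below a cutoff
#'
#' "Diagnosed before the age of 60" is a strict inequality; the percent is
#' rounded half-up to the nearest integer, matching how such proportions
#' are quoted in prose.
#'
#' @param values non-empty numeric vector (`NA`s dropped).
#' @param cutoff threshold.
#' @return list with `count`, `total`, `percent` (integer) and `label`
#'   such as `"18/34 (53%)"`.
#' @export
proportion_below <- function(values, cutoff) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_input("proportion_below: empty input")
  count <- sum(values < cutoff)
  total <- length(values)
  pct <- round_half_up(100 * count / total, 0)
  list(count = count, total = total, percent = pct,
       label = sprintf("%d/%d (%d%%)", count, total, pct))
}

#' Unpaired two-sample t-test on clinical measurements
#'
#' Student's pooled-variance test by default (the conventional reading of
#' "unpaired t-test"); Welch's unequal-variance form is available behind
#' `welch = TRUE` for sensitivity analyses. Reports the two-sided p-value
#' and the 95% confidence interval of the mean difference `a - b`. Groups
#' whose pooled variance is zero (all values identical in both groups) are
#' degenerate and raise an error rather than reporting an infinite
#' statistic.
#'
#' @param group_a,group_b numeric vectors, each with at least two
#'   non-missing values.
#' @param welch use Welch's unequal-variance test.
#' @param conf confidence level for the interval (default 0.95).
#' @return list with `t`, `df`, `p_two_sided`, `mean_a`, `mean_b`,
#'   `mean_diff`, `ci_low`, `ci_high`, `method`.
#' @export
unpaired_t_test <- function(group_a, group_b, welch = FALSE, conf = 0.95) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_input("unpaired_t_test: each group needs at least two values")
  }
  fit <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = !welch, conf.level = conf),
    error = function(e) stop_input("unpaired_t_test: degenerate input (", conditionMessage(e), ")")
  )
  list(t = unname(fit$statistic),
       df = unname(fit$parameter),
       p_two_sided = fit$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b),
       mean_diff = mean(group_a) - mean(group_b),
       ci_low = fit$conf.int[1], ci_high = fit$conf.int[2],
       method = if (welch) "welch" else "student_pooled")
}

#' Summarise a clinical table by variant
#'
#' Age-at-diagnosis and survival summaries for each variant's carriers,
#' plus the proportions diagnosed before given age cutoffs.
#'
#' @param clinical a table from [read_clinical_table()].
#' @param age_cutoffs ages for the "diagnosed before" proportions.
#' @return data frame, one row per variant plus one `all` row.
#' @export
clinical_summary_table <- function(clinical, age_cutoffs = c(50, 60)) {
  groups <- c(list(all = clinical),
              split(clinical, clinical$variant_id))
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    age <- summarize_values(df$age_at_diagnosis)
    surv <- if (any(!is.na(df$survival_months))) {
      summarize_values(df$survival_months)
    } else {
      list(n = 0L, mean = NA_real_, median = NA_real_,
           min = NA_real_, max = NA_real_, sd = NA_real_)
    }
    out <- data.frame(group = g, n = age$n,
                      age_mean = age$mean, age_median = age$median,
                      age_min = age$min, age_max = age$max, age_sd = age$sd,
                      survival_mean = surv$mean, survival_median = surv$median,
                      stringsAsFactors = FALSE)
    for (cut in age_cutoffs) {
      pb <- proportion_below(df$age_at_diagnosis, cut)
      out[[sprintf("pct_before_%d", cut)]] <- pb$percent
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
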