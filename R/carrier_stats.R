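#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Computes the classical two-sided Fisher p-value for a 2x2 contingency
#' table `[[a, b], [c, d]]` (`a` = case carriers, `b` = case non-carriers,
#' `c` = control carriers, `d` = control non-carriers): the sum, over all
#' tables with the observed margins, of conditional hypergeometric
#' probabilities no larger than that of the observed table. Probabilities
#' within a relative tolerance of `1e-7` of the observed one count as tied
#' (the same convention `stats::fisher.test()` uses). When the carrier
#' margin `a + c` is zero the test carries no information and p = 1.
#'
#' The computation is a direct sum over `stats::dhyper()`, which makes a
#' single call cheap enough for the permutation engine to evaluate millions
#' of tables through a memoised lookup.
#'
#' @param table 2x2 integer matrix, or the four cells `a, b, c, d`.
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(1, 43, 1, 1024), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  cells <- as.integer(t(table))
  if (length(cells) != 4L) stop_input("fisher_exact_two_sided: need a 2x2 table")
  if (any(cells < 0)) stop_input("fisher_exact_two_sided: negative cell")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  K <- a + c                      # carrier margin
  if (K == 0L) return(1)
  m <- a + b; n <- c + d          # case / control denominators
  x <- max(0L, K - n):min(K, m)   # support of case-carrier count
  probs <- stats::dhyper(x, m, n, K)
  p_obs <- probs[match(a, x)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

# one-sided (enrichment direction: more carriers in cases) p-value
fisher_one_sided_ge <- function(a, b, c, d) {
  K <- a + c
  if (K == 0L) return(1)
  stats::phyper(a - 1L, a + b, c + d, K, lower.tail = FALSE)
}

#' Carrier frequency with publication-style percent
#'
#' @param carriers carrier count (0 <= carriers <= denominator).
#' @param denominator counting-unit denominator (> 0): participants, or
#'   families for familial study groups.
#' @return list with `carriers`, `denominator`, `frequency` (the
#'   fraction), `percent` (numeric, one decimal, rounded half-up) and
#'   `label` such as `"1/44 (2.3)"`.
#' @examples
#' carrier_frequency(15, 438)$percent # 3.4
#' @export
carrier_frequency <- function(carriers, denominator) {
  if (!is_count(carriers)) stop_input("carrier_frequency: carriers must be a non-negative integer")
  if (!is_count(denominator) || denominator == 0) {
    stop_input("carrier_frequency: denominator must be a positive integer")
  }
  if (carriers > denominator) stop_input("carrier_frequency: carriers exceed denominator")
  freq <- carriers / denominator
  pct <- round_half_up(100 * freq, 1)
  list(carriers = as.integer(carriers), denominator = as.integer(denominator),
       frequency = freq, percent = pct,
       label = sprintf("%d/%d (%s)", carriers, denominator,
                       percent_string(freq, 1)))
}

# Woolf (log-OR) confidence interval; reported only when all cells > 0
odds_ratio_woolf <- function(a, b, c, d, conf = 0.95) {
  if (min(a, b, c, d) == 0L) {
    return(list(or = NA_real_, lo = NA_real_, hi = NA_real_))
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

#' Pairwise case-control carrier comparisons
#'
#' For each variant and each `(case group, control group)` pair, builds the
#' 2x2 carrier table using the groups' counting-unit denominators (families
#' for familial groups) and computes the two-sided Fisher exact p-value,
#' carrier frequencies, and — when all four cells are positive — the sample
#' odds ratio with a 95% Woolf confidence interval. P-values are not
#' adjusted for multiple testing; family-wise error is addressed by the
#' permutation study ([run_permutation_study()]).
#'
#' Variant x group combinations absent from the cohort's carrier table
#' (not assayed) yield rows with `NA` counts and no test.
#'
#' @param x a `cohort`.
#' @param pairs data frame with columns `case_group`, `control_group`.
#' @param variants variant ids to tabulate; defaults to all in the carrier
#'   table.
#' @return data frame, one row per (variant, pair).
#' @export
pairwise_case_control_tests <- function(x, pairs,
                                        variants = sort(unique(x$carriers$variant_id))) {
  stopifnot(inherits(x, "cohort"))
  require_columns(pairs, c("case_group", "control_group"), "pairs")
  unknown <- setdiff(unique(c(pairs$case_group, pairs$control_group)),
                     x$groups$name)
  if (length(unknown) > 0L) {
    stop_input("pairwise_case_control_tests: unknown group(s): ",
               paste(unknown, collapse = ", "))
  }
  nunits <- stats::setNames(x$groups$n_units, x$groups$name)
  rows <- list()
  for (v in variants) {
    for (i in seq_len(nrow(pairs))) {
      cg <- pairs$case_group[i]; kg <- pairs$control_group[i]
      a <- carrier_count(x$carriers, cg, v)
      c_ <- carrier_count(x$carriers, kg, v)
      m <- as.integer(nunits[[cg]]); n <- as.integer(nunits[[kg]])
      if (is.na(a) || is.na(c_)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = v, case_group = cg, control_group = kg,
          case_carriers = a, case_denominator = m,
          control_carriers = c_, control_denominator = n,
          carrier_freq_case = NA_real_, carrier_freq_control = NA_real_,
          case_percent = NA_real_, control_percent = NA_real_,
          p_two_sided = NA_real_, odds_ratio = NA_real_,
          or_ci_low = NA_real_, or_ci_high = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      b <- m - a; d <- n - c_
      p <- fisher_exact_two_sided(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      or <- odds_ratio_woolf(a, b, c_, d)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = v, case_group = cg, control_group = kg,
        case_carriers = a, case_denominator = m,
        control_carriers = c_, control_denominator = n,
        carrier_freq_case = a / m, carrier_freq_control = c_ / n,
        case_percent = round_half_up(100 * a / m, 1),
        control_percent = round_half_up(100 * c_ / n, 1),
        p_two_sided = p, odds_ratio = or$or,
        or_ci_low = or$lo, or_ci_high = or$hi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Any-variant carrier summary per group
#'
#' Sums carrier counts across variants within each group (valid when no
#' participant carries two of the variants, which the analysis assumes and
#' the generator enforces by default) and formats the carrier frequency
#' against the group's counting-unit denominator.
#'
#' @param x a `cohort`.
#' @param variants variant ids to include; default all.
#' @return data frame with one row per group that has at least one assayed
#'   variant: `group`, `carriers`, `denominator`, `frequency`, `percent`,
#'   `label`.
#' @export
carrier_summary <- function(x, variants = unique(x$carriers$variant_id)) {
  stopifnot(inherits(x, "cohort"))
  sub <- x$carriers[x$carriers$variant_id %in% variants, , drop = FALSE]
  rows <- lapply(unique(sub$group), function(g) {
    cf <- carrier_frequency(sum(sub$carriers[sub$group == g]),
                            x$groups$n_units[x$groups$name == g])
    data.frame(group = g, carriers = cf$carriers,
               denominator = cf$denominator, frequency = cf$frequency,
               percent = cf$percent, label = cf$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
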