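# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the Fisher oracle enumerates margin-consistent tables
# with binomial coefficients, the t-test oracle spells out the pooled
# formula.

# two-sided Fisher p by exhaustive enumeration of all tables sharing the
# observed margins; probabilities from choose(), not dhyper()
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  if (K == 0) return(1)
  xs <- max(0, K - n):min(K, m)
  prob <- vapply(xs, function(x) {
    choose(m, x) * choose(n, K - x) / choose(m + n, K)
  }, numeric(1))
  p_obs <- prob[xs == a]
  min(sum(prob[prob <= p_obs * (1 + 1e-7)]), 1)
}

# pooled-variance two-sample t statistic and two-sided p, textbook form
textbook_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# random small 2x2 tables (cells Poisson, bounded total)
random_tables <- function(n, max_total = 40, lambda = 3) {
  out <- vector("list", n)
  i <- 0
  while (i < n) {
    cells <- rpois(4, lambda)
    if (sum(cells) > max_total || sum(cells[c(1, 3)]) == 0) next
    i <- i + 1
    out[[i]] <- cells
  }
  out
}

# minimal two-group cohort with one variant: k carriers among the cases
tiny_cohort <- function(n_cases = 3, n_controls = 3, case_carriers = 2,
                        control_carriers = 0) {
  groups <- data.frame(
    name = c("cases", "controls"), role = c("case", "control"),
    counting_unit = "participant",
    n_units = c(n_cases, n_controls),
    n_participants = c(n_cases, n_controls), stringsAsFactors = FALSE)
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n_cases + n_controls)),
    family_id = "",
    role = rep(c("case", "control"), c(n_cases, n_controls)),
    groups = rep(c("cases", "controls"), c(n_cases, n_controls)),
    is_index = TRUE, stringsAsFactors = FALSE)
  carriers <- data.frame(group = c("cases", "controls"), variant_id = "V1",
                         carriers = c(case_carriers, control_carriers),
                         stringsAsFactors = FALSE)
  cohort(groups, participants, carriers)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "carrierscan", mustWork = TRUE)
}
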