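#' Null calibration of the permutation study
#'
#' Replicates the full permutation study on cohorts whose carriers are
#' allocated uniformly at random over the pooled participants (the
#' permutation null itself), and reports how often each test rejects at
#' `alpha`. A calibrated procedure rejects at close to the nominal rate;
#' because the naive statistic is an exact test on heavily discrete
#' carrier counts, the realized rate sits at or below `alpha` (see the
#' methods vignette).
#'
#' @param x a `cohort` defining the structure and observed carrier totals.
#' @param tests list of [permutation_test()]s.
#' @param n_replicates number of replicate studies.
#' @param n_permutations permutations per replicate study.
#' @param alpha nominal significance level.
#' @param seed integer seed for the whole simulation.
#' @return list with `rates` (per-test rejection rates), `rate_se`
#'   (binomial MC standard errors of the estimated rates), `alpha_se`
#'   (the MC standard error of a nominal-`alpha` binomial at
#'   `n_replicates`), `n_replicates`, `n_permutations`.
#' @export
null_calibration_study <- function(x, tests = default_test_set(),
                                   n_replicates = 200L,
                                   n_permutations = 2000L,
                                   alpha = 0.05, seed) {
  stopifnot(inherits(x, "cohort"))
  engine <- permutation_engine(x)
  totals <- variant_totals(x$carriers)
  cfg <- permutation_config(tests, n_permutations = n_permutations,
                            seed = seed, alpha = alpha)
  set.seed(seed)
  k <- length(tests)
  reject <- matrix(NA, n_replicates, k)
  for (rep_i in seq_len(n_replicates)) {
    null_carriers <- permute_once(engine, totals)
    res <- run_permutation_engine(engine, null_carriers, cfg)
    reject[rep_i, ] <- res$tests$perm_p < alpha
  }
  rates <- colMeans(reject)
  list(rates = stats::setNames(rates, vapply(tests, `[[`, character(1), "name")),
       rate_se = sqrt(rates * (1 - rates) / n_replicates),
       alpha_se = sqrt(alpha * (1 - alpha) / n_replicates),
       n_replicates = n_replicates, n_permutations = n_permutations,
       alpha = alpha)
}

#' Power and type-I error of the carrier enrichment test
#'
#' Simulates case/control carrier counts as independent binomial draws
#' and reports how often the two-sided Fisher exact test detects
#' enrichment at `alpha`. With `case_rate == control_rate` this measures
#' the type-I error of the design (at or below `alpha`: the exact test is
#' conservative on discrete tables).
#'
#' @param n_sims number of simulated cohorts.
#' @param case_n,control_n group sizes.
#' @param case_rate,control_rate per-unit carrier probabilities; defaults
#'   are the high-frequency founder variant's observed rates (15/438
#'   sporadic cases vs 1/1025 sequencing-based controls).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return list with `detection_rate`, `se`, `n_sims`.
#' @export
enrichment_power_study <- function(n_sims = 400L, case_n = 438L,
                                   control_n = 1025L,
                                   case_rate = 15 / 438,
                                   control_rate = 1 / 1025,
                                   alpha = 0.05, seed) {
  set.seed(seed)
  hits <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    a <- stats::rbinom(1, case_n, case_rate)
    c_ <- stats::rbinom(1, control_n, control_rate)
    p <- fisher_exact_two_sided(matrix(c(a, case_n - a, c_, control_n - c_),
                                       2, byrow = TRUE))
    hits[i] <- p < alpha
  }
  rate <- mean(hits)
  list(detection_rate = rate, se = sqrt(rate * (1 - rate) / n_sims),
       n_sims = n_sims)
}

#' Family-wise error rate of independent uniform tests
#'
#' Monte-Carlo check of [estimate_fwer()] against the analytic
#' independence limit `1 - (1 - alpha)^k`.
#'
#' @param k number of tests.
#' @param n_draws simulated studies.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return list with `fwer`, `expected`, `se`, `n_draws`.
#' @export
uniform_fwer_study <- function(k = 5L, n_draws = 100000L, alpha = 0.05, seed) {
  set.seed(seed)
  pmat <- matrix(stats::runif(n_draws * k), n_draws, k)
  fwer <- estimate_fwer(pmat, alpha)
  list(fwer = fwer, expected = 1 - (1 - alpha)^k,
       se = sqrt(fwer * (1 - fwer) / n_draws), n_draws = n_draws)
}
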