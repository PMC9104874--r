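#' Pool participants across study groups
#'
#' Cases can be recruited to more than one study group; the printed group
#' denominators then count the same physical person twice. The pool lists
#' each person exactly once, keeping their group memberships as tags, so
#' a re-allocated carrier status propagates to every membership. With `d`
#' dual-membership participants, the pool size equals total memberships
#' minus `d`.
#'
#' @param x a `cohort`.
#' @return data frame with one row per physical participant:
#'   `participant_id`, `family_id`, `role`, `groups` (semicolon-separated
#'   memberships), `n_memberships`.
#' @export
pool_participants <- function(x) {
  stopifnot(inherits(x, "cohort"))
  p <- x$participants
  out <- data.frame(participant_id = p$participant_id,
                    family_id = p$family_id,
                    role = p$role,
                    groups = p$groups,
                    n_memberships = lengths(strsplit(p$groups, ";", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a carrier-permutation engine for a cohort
#'
#' Precomputes, for every study group, which pool positions belong to it
#' and which counting unit (person, or family for familial groups) each
#' position maps to, so that re-allocating carriers and re-counting group
#' carrier tables is cheap inside long permutation loops.
#'
#' @param x a `cohort`.
#' @return object of class `permutation_engine`.
#' @export
permutation_engine <- function(x) {
  stopifnot(inherits(x, "cohort"))
  pool <- pool_participants(x)
  n_pool <- nrow(pool)
  memberships <- strsplit(pool$groups, ";", fixed = TRUE)
  groups <- x$groups
  unit_of <- list()   # per group: integer unit index per pool position, NA off-group
  for (gi in seq_len(nrow(groups))) {
    g <- groups$name[gi]
    in_g <- vapply(memberships, function(m) g %in% m, logical(1))
    u <- rep(NA_integer_, n_pool)
    if (groups$counting_unit[gi] == "family") {
      fam <- pool$family_id[in_g]
      # dual-membership recruits from non-familial groups carry no family
      # here; they count as their own singleton family
      solo <- which(is.na(fam) | fam == "")
      fam[solo] <- paste0(".solo", solo)
      u[in_g] <- as.integer(factor(fam))
    } else {
      u[in_g] <- seq_len(sum(in_g))
    }
    unit_of[[g]] <- u
  }
  structure(list(pool = pool, n_pool = n_pool, groups = groups,
                 unit_of = unit_of),
            class = "permutation_engine")
}

# group carrier counts for one variant given carrier pool positions:
# number of distinct counting units holding at least one carrier.
count_units <- function(engine, group, carrier_idx) {
  u <- engine$unit_of[[group]][carrier_idx]
  u <- u[!is.na(u)]
  if (length(u) <= 1L) length(u) else length(unique(u))
}

#' Randomly re-allocate observed carriers across the pool
#'
#' Draws one permuted carrier table under the null hypothesis that
#' carrier status is unrelated to study group. Under
#' `allocation_unit = "carrier"` (default) each variant's carriers are a
#' uniform simple random sample, without replacement, of the pooled
#' participants, independently across variants. Under `"variant_block"`
#' each variant's full carrier set lands in a single group drawn with
#' probability proportional to group size, as one block. Group counts are
#' recomputed through the memberships, with family-level deduplication
#' for familial groups; each variant's total carrier count over the pool
#' is preserved. Uses the current RNG state: seed the session (or pass
#' through [run_permutation_study()]) for reproducibility.
#'
#' @param engine a [permutation_engine()] (or a `cohort`, from which one
#'   is built).
#' @param totals named integer vector: carriers to place per variant.
#' @param allocation_unit `"carrier"` or `"variant_block"`.
#' @return carrier table data frame `(group, variant_id, carriers)` with
#'   one row per group x variant.
#' @export
permute_once <- function(engine, totals,
                         allocation_unit = c("carrier", "variant_block")) {
  allocation_unit <- match.arg(allocation_unit)
  if (inherits(engine, "cohort")) engine <- permutation_engine(engine)
  stopifnot(inherits(engine, "permutation_engine"))
  if (any(totals > engine$n_pool)) {
    stop_input("permute_once: carriers exceed pool size")
  }
  idx <- permute_indices(engine, totals, allocation_unit)
  gnames <- engine$groups$name
  rows <- expand.grid(group = gnames, variant_id = names(totals),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$carriers <- mapply(function(g, v) count_units(engine, g, idx[[v]]),
                          rows$group, rows$variant_id, USE.NAMES = FALSE)
  rows[order(rows$variant_id, rows$group), c("group", "variant_id", "carriers")]
}

# carrier pool positions per variant for one permutation
permute_indices <- function(engine, totals, allocation_unit) {
  if (allocation_unit == "carrier") {
    lapply(totals, function(k) {
      if (k == 0L) integer(0) else sample.int(engine$n_pool, k)
    })
  } else {
    sizes <- engine$groups$n_participants
    lapply(totals, function(k) {
      if (k == 0L) return(integer(0))
      ok <- sizes >= k
      g <- engine$groups$name[sample(which(ok), 1L, prob = sizes[ok])]
      members <- which(!is.na(engine$unit_of[[g]]))
      members[sample.int(length(members), k)]
    })
  }
}

#' Define the comparisons for a permutation study
#'
#' Each test compares the summed carrier count of a set of variants in a
#' set of case groups against a set of control groups via the two-sided
#' Fisher exact p-value on counting-unit denominators, mirroring the
#' observed pairwise comparisons.
#'
#' @param name test label.
#' @param variants variant ids entering the numerator.
#' @param case_groups,control_groups group names.
#' @return list of class `permutation_test`.
#' @export
permutation_test <- function(name, variants, case_groups, control_groups) {
  structure(list(name = name, variants = variants,
                 case_groups = case_groups, control_groups = control_groups),
            class = "permutation_test")
}

#' Permutation study configuration
#'
#' @param tests list of [permutation_test()] definitions.
#' @param n_permutations number of random re-allocations (default 5000).
#' @param seed integer seed (required: the study must be reproducible).
#' @param alpha significance level for the family-wise error and joint
#'   significance summaries (default 0.05).
#' @param allocation_unit passed to [permute_once()].
#' @param exhaustive enumerate *all* allocations instead of sampling; only
#'   feasible for small pools (see `max_enumeration`), used to validate
#'   the sampler against exact tail probabilities.
#' @param max_enumeration guard on the number of enumerated allocations.
#' @return list of class `permutation_config`.
#' @export
permutation_config <- function(tests, n_permutations = 5000L, seed,
                               alpha = 0.05,
                               allocation_unit = c("carrier", "variant_block"),
                               exhaustive = FALSE,
                               max_enumeration = 2e5) {
  allocation_unit <- match.arg(allocation_unit)
  stopifnot(length(tests) >= 1L, is_count(n_permutations), n_permutations >= 1,
            alpha > 0, alpha < 1)
  if (missing(seed) || is.null(seed)) stop_input("permutation_config: seed is required")
  structure(list(tests = tests, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alpha = alpha,
                 allocation_unit = allocation_unit,
                 exhaustive = exhaustive, max_enumeration = max_enumeration),
            class = "permutation_config")
}

# observed (case carriers, control carriers) for a test from a carrier table
test_margins <- function(carriers, test) {
  sub <- carriers[carriers$variant_id %in% test$variants, , drop = FALSE]
  a <- sum(sub$carriers[sub$group %in% test$case_groups])
  c_ <- sum(sub$carriers[sub$group %in% test$control_groups])
  c(a = a, c = c_)
}

# memoised Fisher p lookup over (a, c) for fixed denominators
p_lookup <- function(m, n, a_max, c_max) {
  cache <- matrix(NA_real_, a_max + 1L, c_max + 1L)
  function(a, c_) {
    v <- cache[a + 1L, c_ + 1L]
    if (is.na(v)) {
      v <- fisher_exact_two_sided(matrix(c(a, m - a, c_, n - c_), 2, byrow = TRUE))
      cache[a + 1L, c_ + 1L] <<- v
    }
    v
  }
}

#' Run a carrier re-allocation permutation study
#'
#' For each configured test the observed two-sided Fisher p-value is
#' compared with its distribution under random re-allocation of the
#' observed carriers to the pooled participants ([permute_once()]). The
#' per-test permutation p-value uses the add-one estimator
#' `(r + 1) / (B + 1)`, where `r` counts permutations whose naive Fisher
#' p is at most the observed one — never zero, floored at `1/(B+1)`. The
#' study also reports the empirical family-wise error rate (fraction of
#' permutations in which at least one naive test is significant at
#' `alpha`) and the joint significance rate (all tests simultaneously
#' significant), each with a binomial Monte-Carlo standard error.
#'
#' With `exhaustive = TRUE` every distinct allocation is enumerated and
#' the permutation p-value is the exact tail probability
#' `Pr(naive p <= observed p)` under uniform allocation (no add-one
#' adjustment: the estimator is replaced by the exact value).
#'
#' @param x a `cohort`.
#' @param cfg a [permutation_config()].
#' @return list of class `permutation_result`: `tests` (data frame with
#'   observed naive p, permutation p, MC standard error, rejection at
#'   `alpha`), `fwer_estimate`, `fwer_se`, `joint_significance`,
#'   `joint_se`, `n_permutations`, `seed`, `alpha`, `allocation_unit`,
#'   `exhaustive`.
#' @export
run_permutation_study <- function(x, cfg) {
  stopifnot(inherits(x, "cohort"), inherits(cfg, "permutation_config"))
  engine <- permutation_engine(x)
  set.seed(cfg$seed)
  run_permutation_engine(engine, x$carriers, cfg)
}

# core loop, RNG state managed by the caller (lets replicate studies share
# one seeded stream)
run_permutation_engine <- function(engine, carriers, cfg) {
  tests <- cfg$tests
  k <- length(tests)
  totals <- variant_totals(carriers)
  K <- sum(totals)

  nunits <- stats::setNames(engine$groups$n_units, engine$groups$name)
  lookups <- vector("list", k)
  obs_p <- numeric(k)
  for (j in seq_len(k)) {
    tt <- tests[[j]]
    m <- sum(nunits[tt$case_groups]); n <- sum(nunits[tt$control_groups])
    lookups[[j]] <- p_lookup(m, n, a_max = K, c_max = K)
    margins <- test_margins(carriers, tt)
    obs_p[j] <- lookups[[j]](margins[["a"]], margins[["c"]])
  }

  if (cfg$exhaustive) {
    P <- enumerate_allocations(engine, totals, tests, lookups, cfg$max_enumeration)
    B <- nrow(P)
    perm_p <- vapply(seq_len(k), function(j) mean(P[, j] <= obs_p[j]), numeric(1))
    perm_se <- rep(0, k)  # enumeration carries no sampling error
  } else {
    B <- cfg$n_permutations
    P <- matrix(NA_real_, B, k)
    for (b in seq_len(B)) {
      idx <- permute_indices(engine, totals, cfg$allocation_unit)
      P[b, ] <- naive_p_from_idx(engine, idx, tests, lookups)
    }
    r <- vapply(seq_len(k), function(j) sum(P[, j] <= obs_p[j]), numeric(1))
    perm_p <- (r + 1) / (B + 1)
    perm_se <- sqrt((r / B) * (1 - r / B) / B)
  }

  fwer <- estimate_fwer(P, cfg$alpha)
  joint <- mean(apply(P < cfg$alpha, 1, all))
  res <- data.frame(test = vapply(tests, `[[`, character(1), "name"),
                    observed_p = obs_p,
                    perm_p = perm_p,
                    perm_se = perm_se,
                    reject = perm_p < cfg$alpha,
                    stringsAsFactors = FALSE)
  structure(list(tests = res,
                 fwer_estimate = fwer,
                 fwer_se = sqrt(fwer * (1 - fwer) / B),
                 joint_significance = joint,
                 joint_se = sqrt(joint * (1 - joint) / B),
                 n_permutations = B, seed = cfg$seed, alpha = cfg$alpha,
                 allocation_unit = cfg$allocation_unit,
                 exhaustive = cfg$exhaustive),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation study: %d %s (%s allocation)\n",
              x$n_permutations,
              if (x$exhaustive) "enumerated allocations" else "random allocations",
              x$allocation_unit))
  print(x$tests, row.names = FALSE)
  cat(sprintf("FWER at alpha=%.3g: %.4f (MC SE %.4f)\n",
              x$alpha, x$fwer_estimate, x$fwer_se))
  cat(sprintf("Joint significance: %.4f (MC SE %.4f)\n",
              x$joint_significance, x$joint_se))
  invisible(x)
}

# total carriers per variant over the pool (sum of group counts; assumes a
# carrier is counted in one group, which the generator's default honours)
variant_totals <- function(carriers) {
  tot <- tapply(carriers$carriers, carriers$variant_id, sum)
  stats::setNames(as.integer(tot), names(tot))
}

#' Family-wise error rate from a permutation p matrix
#'
#' @param p_matrix B x k matrix of naive per-test p-values, one row per
#'   permutation; entries must be finite and in (0, 1].
#' @param alpha significance level.
#' @return fraction of permutations in which `min p < alpha`.
#' @export
estimate_fwer <- function(p_matrix, alpha = 0.05) {
  p_matrix <- as.matrix(p_matrix)
  if (length(p_matrix) == 0L) stop_input("estimate_fwer: empty p matrix")
  if (any(!is.finite(p_matrix)) || any(p_matrix <= 0 | p_matrix > 1)) {
    stop_input("estimate_fwer: p values must be finite and in (0, 1]")
  }
  mean(apply(p_matrix, 1, min) < alpha)
}

# naive Fisher p of every test for one allocation: the (group x variant)
# carrier counts are computed once, then each test sums its slice
naive_p_from_idx <- function(engine, idx, tests, lookups) {
  gnames <- engine$groups$name
  vnames <- names(idx)
  cnt <- matrix(0L, length(gnames), length(vnames),
                dimnames = list(gnames, vnames))
  for (g in gnames) {
    for (v in vnames) cnt[g, v] <- count_units(engine, g, idx[[v]])
  }
  vapply(seq_along(tests), function(j) {
    tt <- tests[[j]]
    vv <- intersect(tt$variants, vnames)
    a <- sum(cnt[tt$case_groups, vv])
    c_ <- sum(cnt[tt$control_groups, vv])
    lookups[[j]](a, c_)
  }, numeric(1))
}

# enumerate all distinct carrier allocations (small pools only); returns
# the naive p matrix over allocations x tests
enumerate_allocations <- function(engine, totals, tests, lookups, max_enumeration) {
  totals <- totals[totals > 0]
  combos <- lapply(totals, function(k) {
    utils::combn(engine$n_pool, k, simplify = FALSE)
  })
  n_alloc <- prod(vapply(combos, length, numeric(1)))
  if (n_alloc > max_enumeration) {
    stop_input("exhaustive enumeration infeasible: ", n_alloc, " allocations")
  }
  grid <- expand.grid(lapply(combos, seq_along), KEEP.OUT.ATTRS = FALSE)
  P <- matrix(NA_real_, nrow(grid), length(tests))
  for (r in seq_len(nrow(grid))) {
    idx <- stats::setNames(
      lapply(seq_along(combos), function(i) combos[[i]][[grid[r, i]]]),
      names(totals))
    P[r, ] <- naive_p_from_idx(engine, idx, tests, lookups)
  }
  P
}

#' The default five-test comparison set
#'
#' Mirrors the observed carrier comparisons of the study design on the
#' packaged Table-2-style cohort: any-variant carrier rate in (1) all
#' cancer cases, (2) ovarian-cancer families and (3) all families versus
#' sequencing-based controls, and the high-frequency founder variant
#' (`RAD51D:c.620C>T`) in (4) all cases and (5) all families versus all
#' controls.
#'
#' @param variants all candidate variant ids.
#' @param focus variant id carried by both control datasets (tests 4-5).
#' @return list of five [permutation_test()]s.
#' @export
default_test_set <- function(variants = table1_variants()$variant_id,
                             focus = "RAD51D:c.620C>T") {
  list(
    permutation_test("all_cases_vs_seq_controls", variants,
                     c("oc_families", "hboc_families", "sporadic_oc"),
                     "seq_controls"),
    permutation_test("oc_families_vs_seq_controls", variants,
                     "oc_families", "seq_controls"),
    permutation_test("all_families_vs_seq_controls", variants,
                     c("oc_families", "hboc_families"), "seq_controls"),
    permutation_test("focus_all_cases_vs_all_controls", focus,
                     c("oc_families", "hboc_families", "sporadic_oc"),
                     c("seq_controls", "geno_controls")),
    permutation_test("focus_all_families_vs_all_controls", focus,
                     c("oc_families", "hboc_families"),
                     c("seq_controls", "geno_controls"))
  )
}
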