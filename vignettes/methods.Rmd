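---
title: "Methods: carrier enrichment for rare founder variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carrier enrichment for rare founder variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierscan)
```

# The study design

`carrierscan` implements the computational side of a founder-population
case-control design for rare cancer-predisposition variants. The design
has five stages, and the package mirrors them module by module:

1. **Prioritization.** Annotated germline variants from sequenced cases
   are filtered down to candidates worth genotyping.
2. **Carrier enrichment.** Candidate carrier frequencies are compared
   between cancer study groups and population-matched controls with
   two-sided Fisher exact tests.
3. **Permutation study.** The whole battery of tests is calibrated by
   random re-allocation of the observed carriers across the pooled study
   groups.
4. **Loss of heterozygosity.** Tumour/normal allele fractions from
   carriers are classified for somatic loss of the wild-type allele.
5. **Clinical summaries.** Ages at diagnosis and survival are summarized
   and compared between carrier groups.

The individual-level inputs of the original study design (genotypes,
recruitment rosters, clinical records) are restricted biobank data; the
package therefore ships a synthetic-data module whose generators
reproduce the published summary structure exactly, so that every stage is
executable and testable from the repository alone.

# Variant prioritization

## The filtering cascade

A variant survives to candidacy when all of the following pure predicates
hold, so the cascade's outcome is independent of rule order:

* **Call quality** (per genotype call): read depth ≥ 10 and variant
  allele fraction within [0.20, 0.80]. The published rule excludes calls
  *below* 0.20 and *above* 0.80, so both bounds are inclusive on the kept
  side.
* **Consequence class**: silent and intronic variants are removed.
* **Population frequency**: reference-population minor allele frequency
  < 0.01. A *missing* MAF is kept and treated as rare: novel founder
  variants are absent from reference databases by construction, and
  absence of evidence here cannot justify exclusion. Missingness is
  carried as `NA` end to end and is never conflated with zero.
* **Candidacy**: loss-of-function variants (nonsense, frameshift,
  canonical splice) qualify outright. Missense variants qualify only with
  an accepted clinical classification (pathogenic, likely pathogenic,
  VUS — with *conflicting* records accepted as VUS-equivalent, since a
  conflict means credible pathogenic submissions exist) in ClinVar *or*
  under ACMG guidelines, **and** in-silico support.

## In-silico support

Support requires at least one passing tool in any evidence category
(`aggregation_mode = "any_tool"`, the published "at least one of several
in silico tools" reading):

| category     | tools and inclusive thresholds                                      |
|--------------|---------------------------------------------------------------------|
| conservation | GERP ≥ 2.0, PhyloP ≥ 0.2, PhastCons ≥ 0.4                           |
| damaging     | REVEL ≥ 0.4, MetaLR ≥ 0.4, MetaSVM ≥ 0.0, CONDEL ≥ 0.4, CADD ≥ 20, PROVEAN ≤ −2.5 |
| splice       | (dbscSNV ADA ≥ 0.4 **and** RF ≥ 0.4) **or** (MaxEntScan **and** HSF both "affecting") |

The splice rule is a consensus: one splice tool alone never fires.
Categorical labels (`conserved`, `damaging`, `pathogenic`, `benign`,
`tolerated`, `affecting_splicing`, ...) take precedence over numeric
scores when both are present, because curated panels are typically
reported at label level; missing tools contribute nothing. An
`all_categories` mode (every category with non-missing data must pass) is
provided for sensitivity analyses.

Two genuinely open choices are resolved as follows:

* **PROVEAN direction.** The printed threshold ("≥ −2.5") contradicts the
  tool's own convention, under which *lower* scores are more deleterious
  and the canonical cutoff is ≤ −2.5 — and the label profiles of known
  deleterious variants are consistent only with the conventional
  direction. The default is therefore `provean_direction = "le"`, with
  `"ge"` available for annotation stacks that report the opposite sign.
* **Conservation consensus.** Whether conservation support needs one tool
  or all three cannot be discriminated by the packaged panel (all five
  candidates are conserved by all three tools); the any-tool reading is
  used because it matches the stated rule.

# Carrier enrichment

Carrier frequencies use *counting-unit* denominators: families for
familial study groups (a carrier family contributes once to numerator and
denominator; e.g. 49 recruited familial cases collapse to 44 families),
participants elsewhere. Published percentages round half-up to one
decimal, which `carrier_frequency()` reproduces exactly (1/44 → 2.3,
15/438 → 3.4); base R's round-half-to-even is deliberately not used for
formatted output.

`fisher_exact_two_sided()` implements the classical two-sided rule: the
sum of conditional hypergeometric probabilities not exceeding that of the
observed table, with ties resolved at a relative tolerance of `1e-7`
(the same convention as `stats::fisher.test`, with which the
implementation is cross-checked in the tests, alongside a brute-force
enumeration oracle built from binomial coefficients). This definition —
rather than tail-doubling alternatives — reproduces the published
pairwise p-values (0.081, 0.299) exactly at the printed precision. The
computation is a direct `dhyper` sum, cheap enough that the permutation
engine can evaluate millions of tables through a memoised `(a, c)`
lookup keyed on the two carrier counts.

P-values here are deliberately *not* adjusted for multiple testing;
battery-wide error is the permutation study's job. Odds ratios (sample OR
with a 95% Woolf interval) are reported only when all four cells are
positive.

# The permutation study

The recruitment structure motivates the analysis: the same person can be
recruited to two study groups, so the naive tests' denominators overlap
in an unknown-to-them way. The study:

1. **Pools** participants so each physical person appears once
   (`pool_participants()`); with nine dual memberships among 10,061
   memberships the pool holds 10,052 unique persons.
2. **Re-allocates** each variant's observed carrier total as a uniform
   simple random sample (without replacement) of the pool, independently
   across variants (`allocation_unit = "carrier"`, the default). A
   re-allocated carrier propagates to *all* its group memberships, and a
   carrier landing on any member of a family marks that family
   carrier-positive while the denominator stays the family count. The
   alternative `"variant_block"` scheme (a variant's full carrier set
   lands in one group, drawn proportionally to group size) is provided
   because the original study's allocation unit is not published; neither
   scheme is asserted to be the original one, and the original study's
   permutation p-values are accordingly not reproduction targets.
3. **Re-tests** the battery on each allocation with the same Fisher
   statistic as the observed comparisons (a rate-difference statistic
   would be a drop-in alternative; the Fisher p is the default because it
   matches the observed analysis).

Per test, the permutation p is the add-one estimator `(r + 1)/(B + 1)`
with `r` the count of allocations whose naive p is at most the observed
one — never zero, floored at `1/(B+1)`. With `exhaustive = TRUE` every
distinct allocation is enumerated (guarded by `max_enumeration`) and the
exact tail probability replaces the estimator, with no add-one term; the
tests verify the sampler against this enumeration on pools small enough
to enumerate. Study-wide, `estimate_fwer()` reports the fraction of
allocations with at least one naive p below α, and the joint-significance
rate the fraction with *all* tests below α; both carry binomial
Monte-Carlo standard errors.

**Randomness.** One seeded R generator drives the whole study, consumed
sequentially; the implementation is single-threaded, so determinism is
exactly "same seed + same configuration ⇒ identical result". Replicated
simulation studies draw sub-studies from the same stream.

**Calibration and discreteness.** Under the uniform-allocation null the
observed table is exchangeable with the permuted ones, so the rejection
rate at α cannot exceed α beyond Monte-Carlo noise. It can sit *below*
α: carrier counts are small integers, the naive Fisher p takes few
distinct values, and ties push the add-one estimator up. The null
calibration study (`null_calibration_study()`, 200 replicate studies of
B = 2000 allocations over the full cohort structure — sizes chosen to
bound the Monte-Carlo standard error at roughly 1.5 percentage points)
quantifies exactly this: per-test rejection rates within three MC
standard errors of α, at or below it. The same conservativeness appears
in the plain Fisher test's type-I error under binomial sampling of rare
carriers (`enrichment_power_study()` with equal rates).

# Loss of heterozygosity

The published LOH analysis inspected sequencing traces visually; the
package replaces inspection with explicit, configurable thresholds on the
tumour wild-type allele fraction `wtf = 1 − VAF_tumour`:

* `wtf < 0.10` — complete loss;
* `0.10 ≤ wtf < 0.35` — partial loss, read as allelic imbalance
  consistent with contaminating normal stromal cells;
* `wtf ≥ 0.35` — retained heterozygosity;
* uninformative when the normal sample is not heterozygous
  (`VAF_normal` outside [0.2, 0.8]) or tumour depth < 20 reads.

These numbers are this package's declared conventions, *not*
reconstructions of the original visual criteria. Threshold comparisons
are strict-below with a `1e-9` floating-point guard, so a fraction
landing exactly on a cut takes the less-extreme state. The purity link
used by the generator and the recovery tests is the allele-counting
identity `E[VAF] = 1/(2 − p)` under wild-type loss in a tumour of purity
`p` (0.5 when heterozygosity is retained), which implies a recovery
boundary `p > 8/9` for complete loss at the 0.10 cut. The packaged
observation table is synthetic: it encodes the published per-sample LOH
outcomes with representative fractions (0.50 / 0.75 / 0.95), because the
original chromatograms are unavailable in numeric form.

# Clinical summaries

`summarize_values()` reports mean, median, range and the *sample*
standard deviation (`n − 1`; `NA` for a single value).
`proportion_below()` uses strict inequality ("diagnosed before age 60")
and integer half-up percents. `unpaired_t_test()` defaults to Student's
pooled-variance form — the conventional reading of an unadorned
"unpaired t-test" — with Welch's form behind `welch = TRUE`; the
published confidence intervals cannot adjudicate between the two without
the unavailable raw data, so neither published clinical p-value is a
reproduction target. Zero-pooled-variance input is degenerate and raises
an error rather than reporting an infinite statistic.

# The synthetic-data generators

`generate_cohort()` reproduces a cohort specification exactly when given
carrier counts (without-replacement placement over counting units, no
unit carrying two variants — matching the published observation that no
carrier harboured two candidates), or draws binomial counts when given
rates. Familial groups get one index case per family with surplus
recruits assigned to random families; dual recruitment merges membership
pairs across case groups into single persons, preserving printed group
sizes while shrinking the unique-person pool. A merged person recruited
from a non-familial group counts as a singleton family on their familial
side. `generate_variant_panel()` plants known candidates among decoys
whose scores are drawn strictly below every threshold (`sub_threshold`,
so the cascade must recover exactly the planted set) or across thresholds
(`straddling`, so recovery degrades measurably). Decoy scores are drawn
independently per tool; correlation between predictors is out of scope
because only threshold crossings enter the rules engine.

What passing tests on these generators do show: the rules engine, the
counting conventions, the exact test and the permutation machinery are
internally correct and calibrated under the stated sampling assumptions.
What they do not show: robustness to real annotation noise (correlated
predictors, mislabelled consequences), to cryptic relatedness beyond the
modelled family/duplicate structure, or to genotyping error in carrier
counts — none of which the generators emulate.

# Simulation sizes

The repeated-sampling checks use: 1,000 random tables (total N ≤ 40)
against the Fisher enumeration oracle; exhaustive allocation enumeration
on pools of 6–7; 200 replicate permutation studies of B = 2000 for null
calibration; 100,000 draws for the independence-limit FWER; 400 simulated
cohorts each for detection power and null detection at the high-frequency
founder variant's effect size (case rate 15/438 vs control rate 1/1025).
These sizes bound every Monte-Carlo standard error well inside the
acceptance bands while keeping a full run in a few minutes.

# Known limitations

* The permutation allocation scheme is one of two plausible readings of
  the original study; per-test permutation p-values are therefore
  comparable in magnitude but not expected to match the originals.
* HGVS strings are carried verbatim (GRCh37, 1-based) and never validated
  against transcripts; liftover is out of scope.
* The VCF reader maps INFO keys via user configuration and does not parse
  VEP-style packed CSQ strings.
* LOH calling consumes numeric allele fractions; purity is an input to
  the generator, never estimated from data.
* Survival is summarized and t-tested as mean months, matching the
  design it mirrors; no censoring-aware survival modelling is attempted.
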