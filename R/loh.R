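#' Thresholds for loss-of-heterozygosity calling
#'
#' Explicit numeric conventions standing in for visual inspection of
#' sequencing traces. The wild-type allele fraction in tumour is
#' `1 - tumour_vaf`; below `complete_max` the wild-type signal is
#' essentially gone (complete loss), between `complete_max` and
#' `partial_max` it is depleted but present (partial loss — allelic
#' imbalance consistent with contaminating normal stromal cells), and at
#' or above `partial_max` the site reads as retained heterozygous. Calls
#' need `depth_min` tumour reads and a germline-heterozygous normal
#' (`normal_vaf` within `[het_low, het_high]`) to be informative.
#'
#' @param complete_max wild-type fraction below which loss is complete.
#' @param partial_max wild-type fraction below which loss is partial.
#' @param depth_min minimum informative tumour depth.
#' @param het_low,het_high germline heterozygosity window on `normal_vaf`.
#' @return list of class `loh_thresholds`.
#' @export
loh_thresholds <- function(complete_max = 0.10, partial_max = 0.35,
                           depth_min = 20L, het_low = 0.20, het_high = 0.80) {
  stopifnot(0 < complete_max, complete_max < partial_max, partial_max < 1,
            is_count(depth_min))
  structure(list(complete_max = complete_max, partial_max = partial_max,
                 depth_min = as.integer(depth_min),
                 het_low = het_low, het_high = het_high),
            class = "loh_thresholds")
}

loh_states <- function() c("retained_het", "partial_loss", "complete_loss",
                           "uninformative")

#' Classify loss of heterozygosity from tumour/normal allele fractions
#'
#' Vectorised over observations. An observation is `uninformative` when
#' the normal sample is not germline-heterozygous or the tumour depth is
#' below `thresholds$depth_min`; otherwise the call is a pure function of
#' the tumour wild-type fraction `1 - tumour_vaf` (see
#' [loh_thresholds()]). Increasing `tumour_vaf` can only move a call
#' towards `complete_loss`, never away.
#'
#' @param obs data frame with at least `normal_vaf`, `tumour_vaf`,
#'   `tumour_depth` (see [read_loh_table()]).
#' @param thresholds a [loh_thresholds()].
#' @return `obs` with columns `wild_type_fraction` and `state` appended.
#' @export
call_loh <- function(obs, thresholds = loh_thresholds()) {
  require_columns(obs, c("normal_vaf", "tumour_vaf", "tumour_depth"), "LOH observations")
  wtf <- 1 - obs$tumour_vaf
  # strict < at the cuts, guarded against floating-point residue so that a
  # fraction landing exactly on a threshold takes the less-extreme state
  eps <- 1e-9
  state <- ifelse(wtf < thresholds$complete_max - eps, "complete_loss",
                  ifelse(wtf < thresholds$partial_max - eps, "partial_loss",
                         "retained_het"))
  informative <- obs$normal_vaf >= thresholds$het_low &
    obs$normal_vaf <= thresholds$het_high &
    obs$tumour_depth >= thresholds$depth_min
  state[!informative] <- "uninformative"
  obs$wild_type_fraction <- wtf
  obs$state <- state
  obs
}

#' Expected tumour variant allele fraction under a purity mixture
#'
#' Allele-counting for a tumour sample that is a mixture of `purity`
#' tumour cells and `1 - purity` normal cells, at a germline-heterozygous
#' site. With somatic deletion of the wild-type allele every tumour cell
#' contributes one variant allele and no wild-type allele, while each
#' normal cell contributes one of each, so the expected variant fraction
#' is `purity / (2 - purity) + (1 - purity) / (2 - purity) = 1 / (2 - purity)`.
#' With the heterozygous state retained the fraction stays 0.5 at any
#' purity.
#'
#' @param purity tumour-cell fraction in \[0, 1\] (vectorised).
#' @param state `"wild_type_loss"` or `"retained_het"`.
#' @return expected variant allele fraction.
#' @examples
#' expected_variant_fraction(0.6, "wild_type_loss") # 1/1.4
#' @export
expected_variant_fraction <- function(purity, state = c("wild_type_loss", "retained_het")) {
  state <- match.arg(state)
  if (any(purity < 0 | purity > 1)) stop_input("purity must be in [0, 1]")
  if (state == "retained_het") rep(0.5, length(purity)) else 1 / (2 - purity)
}
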