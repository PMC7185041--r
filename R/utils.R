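#' Round half away from zero
#'
#' Presentation rounding used for tabulated proportions. Unlike [round()],
#' which rounds half to even, values exactly halfway between two neighbours
#' are rounded away from zero (0.6135 -> 0.614 at 3 dp), the convention used
#' in banding summary tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(0.4065, 3)  # 0.407, where round() gives 0.406
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The four banding age codes accepted for analysis
#'
#' HY = hatching-year juvenile; SY = second-year (yearling adult);
#' ASY = after-second-year (older adult); AHY = after-hatching-year
#' (adult of undetermined exact age).
#'
#' @return character vector of the valid codes.
#' @export
age_classes <- function() c("HY", "SY", "ASY", "AHY")

# determinate adult classes: exact age known
.determinate <- c("SY", "ASY")

# stop() with call.=FALSE everywhere; small helper keeps messages uniform
abort <- function(...) stop(..., call. = FALSE)

#' Packaged community summary table
#'
#' Per-species sample sizes, age-determination error rates and yearling
#' proportions for the 29 boreal-forest landbird species analysed in the
#' motivating six-year, 35-station banding study: counts of year-unique
#' individuals by age class (SY/ASY/AHY), the number of stations at which
#' each species was captured, and the recapture-verified age error rate with
#' its sample size.
#'
#' @return data.frame with columns `species_code`, `common_name`,
#'   `n_stations`, `n_year_inds`, `n_SY`, `n_ASY`, `n_AHY`, `error_rate`,
#'   `error_n`, `yearling_prop` (the published, 3-dp rounded proportion).
#' @export
#' @examples
#' head(community_table())
community_table <- function() {
  read.csv(system.file("extdata", "table1_counts.csv", package = "yearlingr"),
           stringsAsFactors = FALSE)
}

#' Packaged study-level capture totals
#'
#' Whole-study constants from the motivating banding study: total adult
#' captures including within-season recaptures, the number initially aged AHY
#' in the field, the number of those later re-determined to SY or ASY through
#' photographic review, the count of distinct banded individuals, and the
#' numbers of stations and years.
#'
#' @return named list of integers.
#' @export
study_totals <- function() {
  x <- read.csv(system.file("extdata", "study_totals.csv", package = "yearlingr"),
                stringsAsFactors = FALSE)
  as.list(setNames(as.integer(x$value), x$quantity))
}
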