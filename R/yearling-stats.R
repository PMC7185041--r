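#' Yearling proportion
#'
#' The proportion of determinate-aged adults that are yearlings,
#' SY / (SY + ASY). Adults of undetermined age (AHY) enter neither the
#' numerator nor the denominator; they are handled by the hierarchical model
#' as missing outcomes instead.
#'
#' @param n_SY,n_ASY counts of yearling and older adults (vectorized).
#' @return exact proportion(s); NA (with a warning) where SY + ASY = 0.
#' @export
#' @examples
#' yearling_proportion(119, 75)   # 0.6134... (prints as 0.613 at 3 dp)
yearling_proportion <- function(n_SY, n_ASY) {
  den <- n_SY + n_ASY
  if (any(den == 0)) warning("yearling proportion undefined where SY + ASY = 0")
  ifelse(den > 0, n_SY / den, NA_real_)
}

#' Community mean yearling proportion
#'
#' Unweighted mean of defined per-species yearling proportions. This is the
#' community summary statistic: every species counts equally, regardless of
#' sample size. Contrast [pooled_yearling_proportion()].
#'
#' @param proportions numeric vector of per-species proportions (NAs, from
#'   undefined species, are dropped).
#' @return scalar mean.
#' @export
community_mean_proportion <- function(proportions) {
  p <- proportions[!is.na(proportions)]
  if (!length(p)) abort("no defined proportions supplied")
  mean(p)
}

#' Pooled community yearling proportion
#'
#' Total SY over total (SY + ASY), pooling all individuals regardless of
#' species. Weighted toward abundant species, and therefore generally
#' different from the unweighted species mean of
#' [community_mean_proportion()]; both are reported and must not be
#' conflated.
#'
#' @param n_SY,n_ASY per-species count vectors.
#' @return scalar pooled proportion.
#' @export
pooled_yearling_proportion <- function(n_SY, n_ASY) {
  den <- sum(n_SY) + sum(n_ASY)
  if (den == 0) abort("no determinate-aged adults supplied")
  sum(n_SY) / den
}

#' Species-level yearling table
#'
#' Joins per-species summaries with error-rate estimates into the standard
#' reporting table: species code, recapture-verified age error rate and its
#' sample size, and the exact yearling proportion.
#'
#' @param summaries data.frame from [summarize_species()].
#' @param errors data.frame from [age_error_rates()] (optional; NA columns
#'   if omitted).
#' @return data.frame with columns `species_code`, `error_rate`,
#'   `n_eligible`, `yearling_proportion`.
#' @export
yearling_table <- function(summaries, errors = NULL) {
  out <- data.frame(species_code = summaries$species_code,
                    error_rate = NA_real_, n_eligible = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(errors)) {
    m <- match(out$species_code, errors$species_code)
    out$error_rate <- errors$rate[m]
    out$n_eligible <- errors$n_eligible[m]
  }
  out$yearling_proportion <- yearling_proportion(summaries$n_SY, summaries$n_ASY)
  out
}
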