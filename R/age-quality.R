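#' Propagate a determinate age class across years
#'
#' A yearling (SY) observed in year t is, by definition, an older adult
#' (ASY) in any later year; ASY is absorbing; AHY carries no exact-age
#' information and propagates unchanged.
#'
#' @param age_at_ref age class at the reference capture; one of
#'   `"SY"`, `"ASY"`, `"AHY"`.
#' @param elapsed_years non-negative integer years since the reference.
#' @return the implied age class at reference + `elapsed_years`.
#' @export
#' @examples
#' propagate_age("SY", 0)  # "SY"
#' propagate_age("SY", 2)  # "ASY"
propagate_age <- function(age_at_ref, elapsed_years) {
  if (any(elapsed_years < 0)) abort("elapsed_years must be >= 0")
  if (!all(age_at_ref %in% c("SY", "ASY", "AHY")))
    abort("age_at_ref must be SY, ASY or AHY")
  ifelse(age_at_ref == "SY" & elapsed_years >= 1, "ASY", age_at_ref)
}

#' Age-determination error rates from recapture histories
#'
#' Recaptured birds are aged independently of their previous determinations,
#' so contradictions between captures of the same bird reveal aging errors.
#' For every capture with a determinate (SY/ASY) determination that is
#' preceded by an earlier determinate determination of the same bird, the
#' earlier call is propagated forward with [propagate_age()] and the event is
#' *eligible*; it is *changed* when the propagated and current calls
#' disagree. A legitimate SY-to-ASY transition across a year boundary is not
#' a change; a within-year SY/ASY disagreement always is. Captures whose
#' nearest prior determination is AHY are ineligible (AHY cannot be
#' contradicted). Juvenile (HY) captures do not enter histories.
#'
#' @param records validated capture data.frame from [read_captures()] — the
#'   full capture stream, including within-season recaptures.
#' @return data.frame with columns `species_code`, `n_eligible`,
#'   `n_changed`, `rate` (NA, flagged, when a species has no eligible
#'   events), one row per species present in the stream.
#' @export
age_error_rates <- function(records) {
  x <- records[records$age != "HY", , drop = FALSE]
  x <- x[order(x$band_id, x$year, x$date, x$capture_index), , drop = FALSE]
  sp_of_band <- tapply(x$species_code, x$band_id, `[`, 1L)

  elig <- chng <- integer(0)
  species <- sort(unique(x$species_code))
  elig <- setNames(integer(length(species)), species)
  chng <- setNames(integer(length(species)), species)

  bands <- split(seq_len(nrow(x)), x$band_id)
  for (b in names(bands)) {
    ii <- bands[[b]]
    if (length(ii) < 2L) next
    sp <- sp_of_band[[b]]
    prior_age <- NA_character_; prior_year <- NA_integer_
    for (i in ii) {
      cur <- x$age[i]
      if (cur %in% .determinate && !is.na(prior_age) &&
          prior_age %in% .determinate) {
        expected <- propagate_age(prior_age, x$year[i] - prior_year)
        elig[sp] <- elig[sp] + 1L
        if (expected != cur) chng[sp] <- chng[sp] + 1L
      }
      if (cur %in% .determinate) {       # most recent determinate becomes ref
        prior_age <- cur; prior_year <- x$year[i]
      }
    }
  }
  out <- data.frame(species_code = species,
                    n_eligible = as.integer(elig),
                    n_changed = as.integer(chng),
                    rate = ifelse(elig > 0, chng / pmax(elig, 1L), NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Community mean age-error rate
#'
#' Unweighted mean of the defined per-species error rates; species with no
#' eligible recapture events (rate NA) are excluded.
#'
#' @param estimates data.frame from [age_error_rates()], or a numeric vector
#'   of rates.
#' @return scalar mean rate.
#' @export
community_mean_error <- function(estimates) {
  r <- if (is.data.frame(estimates)) estimates$rate else as.numeric(estimates)
  r <- r[!is.na(r)]
  if (!length(r)) abort("no species with a defined error rate")
  mean(r)
}

#' Proportion of adults aged to an exact class
#'
#' The fraction of adult year-unique individuals whose age was determined to
#' SY or ASY rather than left at AHY.
#'
#' @param n_SY,n_ASY,n_AHY counts, or pass a [summarize_species()] row /
#'   data.frame as `n_SY` with the other arguments missing.
#' @return proportion(s) in \[0,1\]; NA (with a warning) where all three
#'   counts are zero.
#' @export
#' @examples
#' percent_aged(4943, 7224, 1623)  # 0.8823...
percent_aged <- function(n_SY, n_ASY, n_AHY) {
  if (is.data.frame(n_SY)) {
    df <- n_SY
    n_SY <- df$n_SY; n_ASY <- df$n_ASY; n_AHY <- df$n_AHY
  }
  tot <- n_SY + n_ASY + n_AHY
  if (any(tot == 0)) warning("percent_aged undefined where no adults observed")
  ifelse(tot > 0, (n_SY + n_ASY) / tot, NA_real_)
}
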