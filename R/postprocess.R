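#' Species EVI profiles and habitat groups
#'
#' Characterizes where each species' adults were captured along the
#' greenness gradient: `evi_mean` is the mean station-year EVI weighted by
#' the species' adult year-unique captures, `evi_range` the spread (max
#' minus min) of station-year EVI over those captures. Species are then
#' grouped by sample quartiles of the J species means: lowest quartile =
#' successional, middle two = intermediate, highest = mature forest. Sample
#' quantiles use linear interpolation; a species exactly on a boundary goes
#' to the lower group.
#'
#' @param individuals data.frame from [resolve_year_unique()] (adults).
#' @param station_evi data.frame from [station_year_evi()].
#' @param species optional restriction to target species codes.
#' @return data.frame with columns `species_code`, `evi_mean`, `evi_range`,
#'   `n_captures`, `habitat_group` (factor: successional, intermediate,
#'   mature).
#' @export
species_evi_profiles <- function(individuals, station_evi, species = NULL) {
  x <- individuals
  if (!is.null(species)) x <- x[x$species_code %in% species, , drop = FALSE]
  key_x <- paste(x$station_id, x$year)
  key_e <- paste(station_evi$station_id, station_evi$year)
  evi <- station_evi$evi[match(key_x, key_e)]
  ok <- !is.na(evi)
  x <- x[ok, , drop = FALSE]; evi <- evi[ok]
  if (nrow(x) == 0L) abort("no captures with an EVI covariate")

  sp <- sort(unique(x$species_code))
  prof <- data.frame(
    species_code = sp,
    evi_mean = as.numeric(tapply(evi, factor(x$species_code, sp), mean)),
    evi_range = as.numeric(tapply(evi, factor(x$species_code, sp),
                                  function(v) diff(range(v)))),
    n_captures = as.integer(table(factor(x$species_code, sp))),
    stringsAsFactors = FALSE)
  prof$habitat_group <- assign_habitat_groups(prof$evi_mean)
  rownames(prof) <- NULL
  prof
}

#' Quartile-based habitat groups from species EVI means
#'
#' @param evi_means numeric vector of species-level EVI means.
#' @return factor with levels successional, intermediate, mature: lowest
#'   quartile (boundary inclusive), middle two quartiles, upper quartile.
#' @export
assign_habitat_groups <- function(evi_means) {
  q <- quantile(evi_means, c(0.25, 0.75), type = 7, names = FALSE)
  grp <- ifelse(evi_means <= q[1L], "successional",
                ifelse(evi_means > q[2L], "mature", "intermediate"))
  factor(grp, levels = c("successional", "intermediate", "mature"))
}

#' Posterior summary of mean EVI coefficient by habitat group
#'
#' For each posterior draw, averages the species EVI coefficients beta_j
#' within each habitat group; the group mean and its 95% credible interval
#' summarize those draw-level averages.
#'
#' @param fit `yearling_fit` from [fit_yearling_model()].
#' @param profiles data.frame from [species_evi_profiles()] covering the
#'   fitted species.
#' @return data.frame with columns `habitat_group`, `n_species`, `mean`,
#'   `q2.5`, `q97.5`; empty groups are flagged with NA and a warning.
#' @export
group_coefficient_summary <- function(fit, profiles) {
  m <- posterior_matrix(fit)
  beta_cols <- paste0("beta[", fit$species_levels, "]")
  stopifnot(all(beta_cols %in% colnames(m)))
  grp <- profiles$habitat_group[match(fit$species_levels,
                                      profiles$species_code)]
  if (any(is.na(grp)))
    abort("profiles missing for species: ",
          paste(fit$species_levels[is.na(grp)], collapse = ", "))
  out <- lapply(levels(grp), function(g) {
    cols <- beta_cols[grp == g]
    if (!length(cols)) {
      warning("empty habitat group: ", g)
      return(data.frame(habitat_group = g, n_species = 0L, mean = NA_real_,
                        q2.5 = NA_real_, q97.5 = NA_real_))
    }
    gm <- rowMeans(m[, cols, drop = FALSE])
    data.frame(habitat_group = g, n_species = length(cols),
               mean = mean(gm), q2.5 = quantile(gm, 0.025, names = FALSE),
               q97.5 = quantile(gm, 0.975, names = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Meta-regression of species EVI coefficients on their EVI profiles
#'
#' Regresses the posterior-mean species EVI coefficients beta_j on each
#' species' EVI mean and EVI range (both standardized to unit variance), to
#' test whether habitat specialists — species seen over a narrow greenness
#' range — respond more strongly. Point estimates are used as responses;
#' posterior uncertainty in beta_j is not propagated.
#'
#' @param beta_means numeric vector of posterior-mean beta_j, or a
#'   `yearling_fit` from which they are extracted.
#' @param profiles data.frame from [species_evi_profiles()] in matching
#'   species order (matched by `species_code` when a fit is supplied).
#' @return `std_ols_fit` object (coefficients with 95% CIs, R-squared).
#' @export
coefficient_meta_regression <- function(beta_means, profiles) {
  if (inherits(beta_means, "yearling_fit")) {
    fit <- beta_means
    sm <- fit$summary
    beta_means <- sm$mean[match(paste0("beta[", profiles$species_code, "]"),
                                sm$parameter)]
    if (any(is.na(beta_means)))
      abort("fit lacks beta for some profiled species")
  }
  if (length(beta_means) != nrow(profiles))
    abort("beta_means and profiles disagree in length")
  if (nrow(profiles) < 4L) abort("need at least 4 species")
  d <- data.frame(beta = beta_means, evi_mean = profiles$evi_mean,
                  evi_range = profiles$evi_range)
  std_ols("beta", c("evi_mean", "evi_range"), d)
}
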