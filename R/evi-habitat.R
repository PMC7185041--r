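#' Read an EVI cell-value table
#'
#' Long-format CSV of Enhanced Vegetation Index values for the 9 x 9 grid of
#' 0.25 km cells surrounding each station (81 cells per composite), with two
#' June composite dates per station-year. Missing cells are carried as NA,
#' never zero-filled.
#'
#' @param path CSV with columns `station_id`, `year`, `composite_date`,
#'   `cell_row`, `cell_col`, `value`.
#' @return validated data.frame of cell values.
#' @export
read_evi_cells <- function(path) {
  if (!file.exists(path)) abort("EVI cell file not found: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "year", "composite_date", "cell_row", "cell_col",
            "value")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    abort("EVI cell file lacks column(s): ", paste(missing_cols, collapse = ", "))
  x$value <- as.numeric(x$value)
  bad <- !is.na(x$value) & (x$value < -0.2 | x$value > 1)
  if (any(bad)) {
    warning(sum(bad), " EVI values outside [-0.2, 1] set to NA")
    x$value[bad] <- NA_real_
  }
  n_cells <- table(paste(x$station_id, x$year, x$composite_date))
  if (any(n_cells > 81)) abort("composite with more than 81 cells")
  if (any(n_cells < 81))
    warning(sum(n_cells < 81), " composite(s) with fewer than 81 cells; ",
            "absent cells treated as missing")
  x
}

#' Station-year EVI from cell grids
#'
#' Averages the up-to-162 cell values (81 cells x two June composites) into
#' one EVI value per station-year. Missing cells are excluded from the mean
#' and reported through the completeness columns; a station-year with no
#' usable cells gets NA.
#'
#' @param cells data.frame from [read_evi_cells()] (or the generator).
#' @return data.frame with columns `station_id`, `year`, `evi`,
#'   `n_cells_used`, `n_composites`. A warning lists station-years with
#'   fewer than two composites or with no usable cells.
#' @export
station_year_evi <- function(cells) {
  key <- interaction(cells$station_id, cells$year, drop = TRUE)
  agg <- lapply(split(cells, key), function(d) {
    data.frame(station_id = d$station_id[1L], year = d$year[1L],
               evi = if (all(is.na(d$value))) NA_real_
                     else mean(d$value, na.rm = TRUE),
               n_cells_used = sum(!is.na(d$value)),
               n_composites = length(unique(d$composite_date)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$station_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$n_composites < 2))
    warning(sum(out$n_composites < 2),
            " station-year(s) with fewer than two June composites")
  if (any(is.na(out$evi)))
    warning(sum(is.na(out$evi)), " station-year(s) with no usable EVI cells")
  out
}

#' Center a covariate around zero
#'
#' Subtracts the mean and stores it in the `"center"` attribute so model
#' intercepts can be back-transformed to the raw covariate scale.
#'
#' @param values numeric vector (NAs ignored in the mean).
#' @return centered numeric vector with attribute `"center"`.
#' @seealso [uncenter_covariate()]
#' @export
center_covariate <- function(values) {
  if (!length(values)) abort("no values to center")
  m <- mean(values, na.rm = TRUE)
  structure(values - m, center = m)
}

#' Undo [center_covariate()]
#' @param centered vector carrying a `"center"` attribute (or supply `center`).
#' @param center the stored mean, if the attribute was stripped.
#' @return the original values.
#' @export
uncenter_covariate <- function(centered, center = attr(centered, "center")) {
  if (is.null(center)) abort("no stored center found")
  as.numeric(centered) + center
}

#' Station-scale weighted cover metrics
#'
#' Each station holds 1-5 broad habitat types, each with an estimated areal
#' proportion and per-stratum percent cover (understory 0.5-5 m, midstory
#' 5-15 m, upperstory >15 m). The station-scale metric for each stratum is
#' the proportion-weighted average over habitat types.
#'
#' @param habitat data.frame with columns `station_id`, `proportion`,
#'   `cover_understory`, `cover_midstory`, `cover_upperstory` (one row per
#'   habitat type).
#' @return data.frame with one row per station and the three weighted cover
#'   columns. Stations whose habitat-type proportions do not sum to 1 within
#'   0.01 are a hard error.
#' @export
weighted_station_cover <- function(habitat) {
  need <- c("station_id", "proportion", "cover_understory", "cover_midstory",
            "cover_upperstory")
  stopifnot(all(need %in% names(habitat)))
  out <- lapply(split(habitat, habitat$station_id), function(d) {
    s <- sum(d$proportion)
    if (abs(s - 1) > 0.01)
      abort("habitat-type proportions for station ", d$station_id[1L],
            " sum to ", format(s), " (must be 1 +/- 0.01)")
    data.frame(station_id = d$station_id[1L],
               cover_understory = sum(d$proportion * d$cover_understory),
               cover_midstory = sum(d$proportion * d$cover_midstory),
               cover_upperstory = sum(d$proportion * d$cover_upperstory),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Shared OLS-with-standardized-predictors engine. Predictors are z-scored
# (n-1 sd); the response is left on its own scale, so a coefficient is the
# expected response change per 1 SD of predictor. CIs are normal-theory 95%.
std_ols <- function(response, predictors, data, conf = 0.95,
                    kappa_warn = 30) {
  stopifnot(all(c(response, predictors) %in% names(data)))
  d <- data[, c(response, predictors)]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(predictors) + 1L)
    abort("too few complete rows (", nrow(d), ") for the regression")
  scales <- vapply(predictors, function(p) sd(d[[p]]), 1.0)
  if (any(scales == 0)) abort("constant predictor: ",
                              paste(predictors[scales == 0], collapse = ", "))
  z <- d
  for (p in predictors) z[[p]] <- (d[[p]] - mean(d[[p]])) / sd(d[[p]])
  f <- stats::as.formula(paste(response, "~",
                               paste(sprintf("`%s`", predictors), collapse = "+")))
  fit <- lm(f, data = z)
  kn <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (kn > kappa_warn)
    warning("predictors nearly collinear (condition number ",
            format(kn, digits = 3), ")")
  ci <- confint(fit, level = conf)
  cf <- data.frame(term = c("(Intercept)", predictors),
                   estimate = unname(coef(fit)),
                   se = unname(sqrt(diag(stats::vcov(fit)))),
                   ci_lower = unname(ci[, 1L]), ci_upper = unname(ci[, 2L]),
                   stringsAsFactors = FALSE)
  res <- stats::rstandard(fit)
  diagnostics <- list(
    residual_quantiles = quantile(stats::residuals(fit),
                                  c(0, .25, .5, .75, 1), names = TRUE),
    std_resid_vs_normal = quantile(res, c(.025, .25, .5, .75, .975)) -
      qnorm(c(.025, .25, .5, .75, .975)),
    condition_number = kn)
  structure(list(coefficients = cf,
                 r_squared = summary(fit)$r.squared,
                 n = nrow(d), fit = fit, response = response,
                 predictor_means = vapply(predictors, function(p) mean(d[[p]]), 1.0),
                 predictor_sds = scales,
                 diagnostics = diagnostics),
            class = "std_ols_fit")
}

#' @export
print.std_ols_fit <- function(x, ...) {
  cat("Linear regression of", x$response,
      "on standardized predictors (n =", x$n, ")\n")
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' Regression of station-year EVI on habitat covariates
#'
#' Ordinary least-squares fit of June EVI against percent natural cover and
#' years since reclamation, over the disturbed and reclaimed stations
#' (un-reclaimed stations enter with zero years since reclamation).
#' Predictors are standardized to unit variance (sample SD) so coefficients
#' are comparable; the response stays in EVI units. Normal-theory 95%
#' confidence intervals and simple residual diagnostics are attached.
#'
#' @param rows data.frame with columns `evi`, `pct_natural`,
#'   `years_reclaimed` (one row per station-year; at least 3 complete rows).
#' @return object of class `std_ols_fit`: coefficient table with CIs,
#'   `r_squared`, residual diagnostics, and the underlying [lm()] fit.
#' @export
evi_regression <- function(rows) {
  std_ols("evi", c("pct_natural", "years_reclaimed"), rows)
}

#' Years since reclamation for a station-year
#'
#' Data year minus the reclamation start year, clamped at zero; stations
#' never reclaimed (NA start year) count as zero years.
#'
#' @param year data year (vector).
#' @param reclaim_start_year reclamation start year, NA if never reclaimed.
#' @return non-negative integer vector.
#' @export
years_since_reclamation <- function(year, reclaim_start_year) {
  out <- ifelse(is.na(reclaim_start_year), 0L,
                pmax(0L, year - reclaim_start_year))
  as.integer(out)
}
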