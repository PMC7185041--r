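#' Configuration for the synthetic MAPS-like study generator
#'
#' Defines a simulated constant-effort banding study: a station network with
#' a natural/disturbed/reclaimed mix, a species community with true
#' intercepts and EVI slopes drawn from the hierarchical model, a capture
#' process with habitat-dependent abundance, and an observation process with
#' symmetric SY/ASY misclassification and AHY masking. Defaults describe the
#' motivating boreal study: 35 stations (15 natural / 15 disturbed / 5
#' reclaimed) over 6 years, 29 species, a community mean EVI effect of
#' -1.29 with SD 1, a per-determination misclassification rate of 0.042
#' (so the *observed* recapture change rate 2e(1-e) is about 8%), and an
#' AHY-masking probability of 0.118.
#'
#' @param n_natural,n_disturbed,n_reclaimed station counts by class.
#' @param n_years,start_year study window.
#' @param n_species community size J.
#' @param mu_alpha,sigma_alpha,mu_beta,sigma_beta hyperparameters from which
#'   true species intercepts and EVI slopes are drawn (SDs may be 0 for
#'   degenerate scenarios).
#' @param mean_captures expected new adult captures per species-station-year
#'   (Poisson mean before species and habitat adjustment).
#' @param capture_rate_sd lognormal SD of species relative abundance.
#' @param abundance_tilt_sd SD of the per-species log-linear tilt of the
#'   Poisson mean in centered EVI (habitat preference; sign random by
#'   species).
#' @param misclass_rate probability e that a single determinate age
#'   determination is flipped (SY <-> ASY), independently per determination.
#' @param ahy_mask_rate probability m that a bird-year is masked to AHY
#'   (masking is per bird-year and overrides determinate calls; independent
#'   of true age).
#' @param within_year_recapture Poisson mean of extra same-year captures per
#'   bird-year.
#' @param between_year_return probability a bird is captured again the
#'   following year.
#' @param hy_fraction juvenile (HY) captures per adult expected capture.
#' @param evi_natural_mean,evi_station_sd mean and between-station SD of
#'   June EVI at natural stations.
#' @param evi_initial EVI of freshly disturbed, unvegetated ground.
#' @param evi_parity_years reclamation age at which a reclaimed station's
#'   EVI reaches the natural mean (linear rise, exact parity at and beyond).
#' @param evi_year_sd,evi_cell_sd year-to-year and within-grid cell noise.
#' @param reclaim_age_min,reclaim_age_max range of reclamation ages (years)
#'   at the first study year across reclaimed stations.
#' @param june_dates the two June composite dates (month-day strings).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_natural = 15, n_disturbed = 15, n_reclaimed = 5,
                       n_years = 6, start_year = 2011, n_species = 29,
                       mu_alpha = -0.38, sigma_alpha = 0.5,
                       mu_beta = -1.29, sigma_beta = 1,
                       mean_captures = 1.75, capture_rate_sd = 0.6,
                       abundance_tilt_sd = 5,
                       misclass_rate = 0.042, ahy_mask_rate = 0.118,
                       within_year_recapture = 0.36,
                       between_year_return = 0.08, hy_fraction = 0.3,
                       evi_natural_mean = 0.55, evi_station_sd = 0.03,
                       evi_initial = 0.25, evi_parity_years = 20,
                       evi_year_sd = 0.015, evi_cell_sd = 0.05,
                       reclaim_age_min = 1, reclaim_age_max = 29,
                       june_dates = c("06-10", "06-26")) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#' @param cfg list of generator parameters.
#' @return the config, invisibly; hard error on violated invariants.
#' @export
validate_sim_config <- function(cfg) {
  probs <- c("misclass_rate", "ahy_mask_rate", "between_year_return")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(p, " must be in [0, 1]")
  nonneg <- c("mean_captures", "capture_rate_sd", "within_year_recapture",
              "hy_fraction", "sigma_alpha", "sigma_beta", "evi_station_sd",
              "evi_year_sd", "evi_cell_sd", "abundance_tilt_sd")
  for (p in nonneg) if (cfg[[p]] < 0) abort(p, " must be >= 0")
  if (cfg$n_species < 1 || cfg$n_years < 1) abort("need >= 1 species and year")
  if (cfg$n_natural + cfg$n_disturbed + cfg$n_reclaimed < 1)
    abort("need >= 1 station")
  if (cfg$evi_parity_years <= 0) abort("evi_parity_years must be positive")
  if (length(cfg$june_dates) != 2L) abort("exactly two June composite dates")
  invisible(cfg)
}

#' Named scenario presets
#'
#' Ready-made generator configurations: `paper_like` (the defaults — the
#' motivating study's scale and effect sizes), `null` (no EVI effect in any
#' species: mu_beta = 0, sigma_beta = 0), `error_free` (perfect aging:
#' misclassification and AHY masking off) and `high_missingness` (40% of
#' bird-years masked to AHY).
#'
#' @return named list of `sim_config` objects.
#' @export
scenario_presets <- function() {
  list(
    paper_like = sim_config(),
    null = sim_config(mu_beta = 0, sigma_beta = 0),
    error_free = sim_config(misclass_rate = 0, ahy_mask_rate = 0),
    high_missingness = sim_config(ahy_mask_rate = 0.4)
  )
}

#' Write / read a generator config as YAML
#' @param cfg `sim_config` object.
#' @param path YAML file path.
#' @return `read_sim_config()` returns the validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_config, cfg)
}

#' Simulate station network, EVI grids and habitat tables
#'
#' Natural stations sit at the natural EVI mean (plus between-station
#' noise); disturbed stations scale with their percent natural cover;
#' reclaimed stations rise linearly with reclamation age, reaching the
#' natural mean exactly at `evi_parity_years` and staying there. Each
#' station-year gets two June composites of 81 cells (9 x 9 grid of 0.25 km
#' cells) around the station-year mean.
#'
#' @param config `sim_config` object.
#' @param seed integer seed.
#' @return list with `cells` (long EVI cell table as read by
#'   [read_evi_cells()]), `habitat` (long habitat-type table with station
#'   attributes, as used by [weighted_station_cover()]), `stations`
#'   (station attribute table) and `station_year` (ground truth:
#'   `station_id`, `year`, `evi_true`, `class`, `pct_natural`,
#'   `years_reclaimed`).
#' @export
simulate_evi <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config
  n_sta <- cfg$n_natural + cfg$n_disturbed + cfg$n_reclaimed
  cls <- rep(c("natural", "disturbed", "reclaimed"),
             c(cfg$n_natural, cfg$n_disturbed, cfg$n_reclaimed))
  stations <- data.frame(
    station_id = sprintf("ST%02d", seq_len(n_sta)),
    class = cls,
    pct_natural = round(c(runif(cfg$n_natural, 91, 98),
                          runif(cfg$n_disturbed, 50, 88),
                          runif(cfg$n_reclaimed, 5, 40)), 1),
    stringsAsFactors = FALSE)
  ages1 <- cfg$reclaim_age_min:cfg$reclaim_age_max
  age_at_start <- sample(ages1, cfg$n_reclaimed,
                         replace = cfg$n_reclaimed > length(ages1))
  stations$reclaim_start_year <- NA_integer_
  stations$reclaim_start_year[cls == "reclaimed"] <-
    as.integer(cfg$start_year - age_at_start)
  station_effect <- rnorm(n_sta, 0, cfg$evi_station_sd)

  years <- as.integer(cfg$start_year) + seq_len(cfg$n_years) - 1L
  sy <- expand.grid(si = seq_len(n_sta), year = years)
  sy$station_id <- stations$station_id[sy$si]
  sy$class <- stations$class[sy$si]
  sy$pct_natural <- stations$pct_natural[sy$si]
  sy$years_reclaimed <- years_since_reclamation(
    sy$year, stations$reclaim_start_year[sy$si])
  mix <- ifelse(sy$class == "natural", 1,
                ifelse(sy$class == "disturbed", sy$pct_natural / 100,
                       pmin(sy$years_reclaimed / cfg$evi_parity_years, 1)))
  base <- cfg$evi_initial + (cfg$evi_natural_mean - cfg$evi_initial) * mix +
    station_effect[sy$si]
  sy$evi_true <- pmin(1, pmax(-0.2, base + rnorm(nrow(sy), 0, cfg$evi_year_sd)))

  grid <- expand.grid(cell_row = 1:9, cell_col = 1:9)
  n_comp <- nrow(sy) * 2L
  cells <- data.frame(
    station_id = rep(sy$station_id, each = 162L),
    year = rep(sy$year, each = 162L),
    composite_date = paste0(rep(sy$year, each = 162L), "-",
                            rep(rep(cfg$june_dates, each = 81L), nrow(sy))),
    cell_row = rep(grid$cell_row, n_comp),
    cell_col = rep(grid$cell_col, n_comp),
    stringsAsFactors = FALSE)
  cells$value <- pmin(1, pmax(-0.2, rep(sy$evi_true, each = 162L) +
                                rnorm(nrow(cells), 0, cfg$evi_cell_sd)))

  # in-situ habitat table: 1-3 broad types per station, covers tied to the
  # station's vegetation maturity at the in-situ assessment (last study year)
  mix_last <- mix[sy$year == max(years)][order(sy$si[sy$year == max(years)])]
  hab <- lapply(seq_len(n_sta), function(i) {
    k <- sample(1:3, 1L)
    w <- rgamma(k, 4, 1); w <- w / sum(w)
    m <- mix_last[i]
    data.frame(
      station_id = stations$station_id[i],
      habitat_type = paste0("H", seq_len(k)),
      proportion = w,
      cover_understory = pmin(100, pmax(0, runif(k, 20, 70))),
      cover_midstory = pmin(100, pmax(0, 5 + 65 * m + rnorm(k, 0, 8))),
      cover_upperstory = pmin(100, pmax(0, ifelse(stations$class[i] == "natural",
                                                  runif(k, 30, 65),
                                                  runif(k, 0, 15)))),
      class = stations$class[i],
      pct_natural = stations$pct_natural[i],
      reclaim_start_year = stations$reclaim_start_year[i],
      stringsAsFactors = FALSE)
  })
  habitat <- do.call(rbind, hab)
  rownames(habitat) <- NULL

  list(cells = cells, habitat = habitat, stations = stations,
       station_year = sy[, c("station_id", "year", "evi_true", "class",
                             "pct_natural", "years_reclaimed")])
}

# flip SY <-> ASY
.flip_age <- function(age) ifelse(age == "SY", "ASY", "SY")

#' Simulate a capture dataset with known ground truth
#'
#' Runs the inferential model forward. For each species, station and year,
#' the number of newly captured adults is Poisson with a species abundance
#' rate tilted log-linearly in centered EVI (habitat preference); each
#' bird's true age is yearling (SY) with probability
#' `plogis(alpha_j + beta_j * evi_centered)`, and older (ASY) otherwise.
#' Birds return the following year with probability `between_year_return`
#' (always ASY thereafter). The observation process then masks each
#' bird-year to AHY with probability `ahy_mask_rate` (overriding all of that
#' year's determinations) and, for unmasked bird-years, flips each
#' independent determination SY <-> ASY with probability `misclass_rate`.
#' Extra same-year captures (with fresh independent determinations) occur at
#' Poisson rate `within_year_recapture`; juvenile (HY) captures are added at
#' `hy_fraction` of the adult rate.
#'
#' @param config `sim_config`.
#' @param evi_truth the `station_year` truth table from [simulate_evi()].
#' @param seed integer seed.
#' @return list with `captures` (analysis-ready capture data.frame matching
#'   the [read_captures()] schema, plus derived `year` and `capture_index`)
#'   and `truth` (class `sim_truth`: species-level `alpha`/`beta`, the
#'   hyperparameters, per-bird-year true ages and mask indicators,
#'   per-capture error indicators, the EVI centering constant, and the adult
#'   bird-year count `n_adult_bird_years`).
#' @export
simulate_captures <- function(config = sim_config(), evi_truth, seed = 1) {
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config
  J <- cfg$n_species
  sp_codes <- make_species_codes(J)
  alpha <- rnorm(J, cfg$mu_alpha, cfg$sigma_alpha)
  beta <- if (cfg$sigma_beta > 0) rnorm(J, cfg$mu_beta, cfg$sigma_beta)
          else rep(cfg$mu_beta, J)
  lambda <- cfg$mean_captures *
    exp(rnorm(J, 0, cfg$capture_rate_sd) - cfg$capture_rate_sd^2 / 2)
  tilt <- rnorm(J, 0, cfg$abundance_tilt_sd)

  evi_center <- mean(evi_truth$evi_true)
  evi_c <- evi_truth$evi_true - evi_center
  n_sy <- nrow(evi_truth)

  # new adult birds per species x station-year
  g <- expand.grid(sp = seq_len(J), syi = seq_len(n_sy))
  lam <- lambda[g$sp] * exp(tilt[g$sp] * evi_c[g$syi])
  g$n_new <- rpois(nrow(g), lam)
  first <- g[rep(seq_len(nrow(g)), g$n_new), c("sp", "syi"), drop = FALSE]
  n_birds <- nrow(first)
  if (n_birds == 0L) abort("no birds simulated; increase mean_captures")
  first$bird <- seq_len(n_birds)
  p_sy <- plogis(alpha[first$sp] + beta[first$sp] * evi_c[first$syi])
  first$true_age <- ifelse(rbinom(n_birds, 1L, p_sy) == 1L, "SY", "ASY")

  years <- sort(unique(evi_truth$year))
  sy_key <- paste(evi_truth$station_id, evi_truth$year)
  # bird-years: first captures plus between-year returns (always ASY later)
  by <- data.frame(bird = first$bird, sp = first$sp, syi = first$syi,
                   true_age = first$true_age, stringsAsFactors = FALSE)
  for (t in years[-length(years)]) {
    in_t <- by[evi_truth$year[by$syi] == t, , drop = FALSE]
    if (!nrow(in_t)) next
    ret <- in_t[runif(nrow(in_t)) < cfg$between_year_return, , drop = FALSE]
    if (nrow(ret)) {
      nxt <- match(paste(evi_truth$station_id[ret$syi], t + 1L), sy_key)
      ok <- !is.na(nxt)
      if (any(ok)) {
        by <- rbind(by, data.frame(bird = ret$bird[ok], sp = ret$sp[ok],
                                   syi = nxt[ok], true_age = "ASY",
                                   stringsAsFactors = FALSE))
      }
    }
  }
  n_by <- nrow(by)
  by$masked <- runif(n_by) < cfg$ahy_mask_rate
  by$n_caps <- 1L + rpois(n_by, cfg$within_year_recapture)
  by$band_id <- sprintf("B%06d", by$bird)
  by$species_code <- sp_codes[by$sp]
  by$station_id <- evi_truth$station_id[by$syi]
  by$year <- evi_truth$year[by$syi]

  cap <- by[rep(seq_len(n_by), by$n_caps), , drop = FALSE]
  n_cap <- nrow(cap)
  cap$error <- !cap$masked & runif(n_cap) < cfg$misclass_rate
  cap$age <- ifelse(cap$masked, "AHY",
                    ifelse(cap$error, .flip_age(cap$true_age), cap$true_age))
  cap$date <- as.Date(paste0(cap$year, "-06-05")) + sample(0:59, n_cap,
                                                           replace = TRUE)

  # juveniles: HY captures, never recaptured, excluded from adult analyses
  g$n_hy <- rpois(nrow(g), cfg$hy_fraction * lam)
  hy <- g[rep(seq_len(nrow(g)), g$n_hy), c("sp", "syi"), drop = FALSE]
  if (nrow(hy)) {
    hy_df <- data.frame(
      band_id = sprintf("J%06d", seq_len(nrow(hy))),
      species_code = sp_codes[hy$sp],
      station_id = evi_truth$station_id[hy$syi],
      year = evi_truth$year[hy$syi],
      age = "HY",
      date = as.Date(paste0(evi_truth$year[hy$syi], "-07-01")) +
        sample(0:30, nrow(hy), replace = TRUE),
      masked = NA, error = NA, true_age = "HY",
      stringsAsFactors = FALSE)
  } else hy_df <- NULL

  keep_cols <- c("band_id", "species_code", "station_id", "year", "age",
                 "date", "masked", "error", "true_age")
  cap_all <- rbind(cap[, keep_cols], if (!is.null(hy_df)) hy_df[, keep_cols])
  cap_all <- cap_all[order(cap_all$band_id, cap_all$year, cap_all$date), ,
                     drop = FALSE]
  key <- paste(cap_all$band_id, cap_all$year)
  cap_all$capture_index <- stats::ave(seq_len(nrow(cap_all)), key,
                                      FUN = seq_along)
  rownames(cap_all) <- NULL

  captures <- cap_all[, c("band_id", "species_code", "station_id", "year",
                          "date", "age", "capture_index")]
  truth <- structure(list(
    species = data.frame(species_code = sp_codes, alpha = alpha, beta = beta,
                         lambda = lambda, tilt = tilt,
                         stringsAsFactors = FALSE),
    hyper = list(mu_alpha = cfg$mu_alpha, sigma_alpha = cfg$sigma_alpha,
                 mu_beta = cfg$mu_beta, sigma_beta = cfg$sigma_beta),
    bird_years = by[, c("band_id", "species_code", "station_id", "year",
                        "true_age", "masked", "n_caps")],
    capture_truth = cap_all[, c("band_id", "year", "capture_index", "age",
                                "true_age", "masked", "error")],
    evi_center = evi_center,
    n_adult_bird_years = n_by,
    config = cfg), class = "sim_truth")
  list(captures = captures, truth = truth)
}

#' Simulate a complete study (EVI + captures)
#'
#' Convenience wrapper running [simulate_evi()] with `seed` and
#' [simulate_captures()] with `seed + 1`.
#'
#' @param config `sim_config`.
#' @param seed integer seed.
#' @return list with `evi` (from [simulate_evi()]), `captures` and `truth`
#'   (from [simulate_captures()]).
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  evi <- simulate_evi(config, seed)
  cap <- simulate_captures(config, evi$station_year, seed + 1L)
  list(evi = evi, captures = cap$captures, truth = cap$truth)
}

#' Synthetic four-letter species codes
#' @param n number of codes.
#' @return character vector of distinct 4-letter codes (SAAA, SAAB, ...).
#' @export
make_species_codes <- function(n) {
  if (n > 26^3) abort("too many species")
  i <- seq_len(n) - 1L
  paste0("S", LETTERS[i %/% 676L + 1L], LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}
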