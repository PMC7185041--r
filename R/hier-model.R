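#' Assemble model data for the hierarchical yearling model
#'
#' Joins year-unique individuals to station-year EVI covariates and codes the
#' outcome: 1 for a yearling (SY), 0 for an older adult (ASY), and NA for an
#' adult of undetermined age (AHY) — AHY birds are *missing* outcomes, never
#' zeros. The covariate attached to each individual is centered around zero
#' (mean stored for back-transformation). Individuals whose station-year has
#' no EVI value are dropped and counted.
#'
#' @param individuals data.frame from [resolve_year_unique()].
#' @param station_evi data.frame from [station_year_evi()] (`station_id`,
#'   `year`, `evi`).
#' @param species optional character vector restricting to the target
#'   species (e.g. from [filter_target_species()]).
#' @return object of class `yearling_model_data`: list with `y` (0/1/NA),
#'   `species_idx` (1..J), `species_levels`, `evi` (centered), `evi_center`,
#'   `station_id`, `year`, `n`, `J`, `n_dropped`.
#' @export
build_model_data <- function(individuals, station_evi, species = NULL) {
  x <- individuals
  if (!is.null(species)) x <- x[x$species_code %in% species, , drop = FALSE]
  if (nrow(x) == 0L) abort("no individuals left after species restriction")
  key_x <- paste(x$station_id, x$year)
  key_e <- paste(station_evi$station_id, station_evi$year)
  evi_raw <- station_evi$evi[match(key_x, key_e)]
  keep <- !is.na(evi_raw)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("build_model_data: dropped ", n_dropped,
            " individual(s) with no station-year EVI value")
  x <- x[keep, , drop = FALSE]
  evi_raw <- evi_raw[keep]
  if (nrow(x) == 0L) abort("no individuals with an EVI covariate")

  evi_c <- center_covariate(evi_raw)
  lev <- sort(unique(x$species_code))
  y <- ifelse(x$resolved_age == "SY", 1L,
              ifelse(x$resolved_age == "ASY", 0L, NA_integer_))
  structure(list(
    y = as.integer(y),
    species_idx = match(x$species_code, lev),
    species_levels = lev,
    evi = as.numeric(evi_c),
    evi_center = attr(evi_c, "center"),
    station_id = x$station_id, year = x$year,
    n = nrow(x), J = length(lev), n_dropped = n_dropped
  ), class = "yearling_model_data")
}

#' @export
print.yearling_model_data <- function(x, ...) {
  cat("Yearling model data:", x$n, "individuals,", x$J, "species;",
      sum(is.na(x$y)), "unknown-age (AHY) outcomes;",
      x$n_dropped, "dropped (no covariate)\n")
  invisible(x)
}

#' Log unnormalized posterior of the hierarchical model
#'
#' The model is logit(p_i) = alpha_j[i] + beta_j[i] * evi_i with species
#' effects alpha_j ~ N(mu_alpha, sigma_alpha^2), beta_j ~ N(mu_beta,
#' sigma_beta^2), hyperpriors mu ~ N(0, `mu_prior_sd`^2) and sigma ~
#' Uniform(0, `sigma_upper`). Missing (AHY) outcomes contribute nothing to
#' the likelihood. This reference implementation defines the target density
#' that the sampler explores; it is also usable for MAP diagnostics.
#'
#' @param data `yearling_model_data` from [build_model_data()].
#' @param params list with `alpha`, `beta` (length-J vectors), `mu_alpha`,
#'   `mu_beta`, `sigma_alpha`, `sigma_beta`.
#' @param mu_prior_sd,sigma_upper hyperprior constants.
#' @return scalar log density (up to an additive constant); `-Inf` for
#'   non-finite parameters or sigmas outside (0, `sigma_upper`].
#' @export
log_unnormalized_posterior <- function(data, params, mu_prior_sd = 10,
                                       sigma_upper = 10) {
  p <- params
  vals <- c(p$alpha, p$beta, p$mu_alpha, p$mu_beta, p$sigma_alpha,
            p$sigma_beta)
  if (any(!is.finite(vals))) return(-Inf)
  if (p$sigma_alpha <= 0 || p$sigma_alpha > sigma_upper ||
      p$sigma_beta <= 0 || p$sigma_beta > sigma_upper) return(-Inf)
  stopifnot(length(p$alpha) == data$J, length(p$beta) == data$J)

  obs <- !is.na(data$y)
  eta <- p$alpha[data$species_idx[obs]] +
    p$beta[data$species_idx[obs]] * data$evi[obs]
  # y*eta - log(1 + exp(eta)), stabilized
  ll <- sum(data$y[obs] * eta - ifelse(eta > 35, eta,
                                       ifelse(eta < -35, 0, log1p(exp(eta)))))
  lp <- sum(dnorm(p$alpha, p$mu_alpha, p$sigma_alpha, log = TRUE)) +
    sum(dnorm(p$beta, p$mu_beta, p$sigma_beta, log = TRUE)) +
    dnorm(p$mu_alpha, 0, mu_prior_sd, log = TRUE) +
    dnorm(p$mu_beta, 0, mu_prior_sd, log = TRUE) -
    2 * log(sigma_upper)
  ll + lp
}

#' Fit the multispecies hierarchical yearling model
#'
#' Samples the posterior of the Bernoulli/logit model described in
#' [log_unnormalized_posterior()] by adaptive Metropolis-within-Gibbs:
#' random-walk Metropolis on each species intercept and slope (proposal
#' scales tuned during warmup toward 44% acceptance), conjugate Gibbs draws
#' for the hyper-means, and inverse-gamma Gibbs draws for the hyper-variances
#' under the Uniform(0, `sigma_upper`) prior on the SDs. AHY individuals
#' (missing outcomes) are uninformative under this likelihood and are
#' excluded from it; their latent ages can be imputed afterwards with
#' [impute_unknown_ages()].
#'
#' @param data `yearling_model_data` from [build_model_data()].
#' @param chains number of independent chains (default 3).
#' @param iter post-warmup iterations per chain (default 2000).
#' @param warmup warmup (adaptation) iterations per chain (default 2000).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param mu_prior_sd,sigma_upper hyperprior constants.
#' @param hyper_fixed optional named list pinning any of `mu_alpha`,
#'   `mu_beta`, `sigma_alpha`, `sigma_beta` to constants (used e.g. for
#'   single-species fits with fixed wide priors).
#' @param target_accept Metropolis adaptation target (default 0.44, the
#'   optimum for one-dimensional random-walk updates).
#' @return object of class `yearling_fit`: `draws` (a [coda::mcmc.list]),
#'   `summary` (per-parameter mean, sd, 2.5/97.5% quantiles, split R-hat,
#'   effective sample size), `species_levels`, `evi_center`, `config`, and
#'   `flags` (convergence and one-class-species warnings). Emits a warning
#'   when any monitored parameter has R-hat > 1.1 or ESS < 400.
#' @export
fit_yearling_model <- function(data, chains = 3, iter = 2000, warmup = 2000,
                               seed = 1, mu_prior_sd = 10, sigma_upper = 10,
                               hyper_fixed = NULL, target_accept = 0.44) {
  stopifnot(inherits(data, "yearling_model_data"))
  obs <- !is.na(data$y)
  if (!any(obs)) abort("no determinate-aged individuals to fit")
  y <- data$y[obs]
  sp0 <- data$species_idx[obs] - 1L
  evi <- data$evi[obs]
  J <- data$J

  # species observed with a single outcome class: allowed, but flagged
  cls <- tapply(y, data$species_idx[obs], function(v) length(unique(v)))
  one_class <- data$species_levels[as.integer(names(cls))[cls < 2]]
  missing_sp <- setdiff(seq_len(J), unique(data$species_idx[obs]))
  if (length(missing_sp))
    warning("species with no determinate outcomes: ",
            paste(data$species_levels[missing_sp], collapse = ", "))

  hf <- c(mu_alpha = NA_real_, mu_beta = NA_real_, sigma_alpha = NA_real_,
          sigma_beta = NA_real_)
  if (!is.null(hyper_fixed)) {
    bad <- setdiff(names(hyper_fixed), names(hf))
    if (length(bad)) abort("unknown hyper_fixed entries: ",
                           paste(bad, collapse = ", "))
    hf[names(hyper_fixed)] <- unlist(hyper_fixed)
  }
  fix <- !is.na(hf)
  fix_val <- ifelse(fix, hf, 0)

  par_names <- c(paste0("alpha[", data$species_levels, "]"),
                 paste0("beta[", data$species_levels, "]"),
                 "mu_alpha", "mu_beta", "sigma_alpha", "sigma_beta")

  chain_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    init <- list(alpha = rnorm(J, 0, 0.2), beta = rnorm(J, 0, 0.2),
                 mu_alpha = rnorm(1, 0, 0.2), mu_beta = rnorm(1, 0, 0.2),
                 sigma_alpha = runif(1, 0.5, 1.5),
                 sigma_beta = runif(1, 0.5, 1.5))
    res <- ymg_sample_chain(y, sp0, evi, J, as.integer(warmup),
                            as.integer(iter), init, mu_prior_sd, sigma_upper,
                            fix, fix_val, target_accept)
    m <- res$draws
    colnames(m) <- par_names
    chain_list[[ch]] <- coda::mcmc(m, start = warmup + 1L, thin = 1L)
  }
  draws <- coda::mcmc.list(chain_list)

  all_mat <- do.call(rbind, lapply(chain_list, as.matrix))
  const_par <- apply(all_mat, 2L, function(v) var(v) == 0)
  rhat <- rep(NA_real_, length(par_names))
  if (chains >= 2) {
    for (k in seq_along(par_names)) {
      if (const_par[k]) next
      g <- try(coda::gelman.diag(draws[, k, drop = FALSE],
                                 autoburnin = FALSE)$psrf[1L], silent = TRUE)
      if (!inherits(g, "try-error")) rhat[k] <- g
    }
  }
  ess <- rep(NA_real_, length(par_names))
  ess[!const_par] <- as.numeric(coda::effectiveSize(draws[, !const_par,
                                                          drop = FALSE]))
  smry <- data.frame(
    parameter = par_names,
    mean = colMeans(all_mat),
    sd = apply(all_mat, 2L, sd),
    q2.5 = apply(all_mat, 2L, quantile, 0.025),
    q97.5 = apply(all_mat, 2L, quantile, 0.975),
    rhat = rhat, ess = ess, stringsAsFactors = FALSE)
  rownames(smry) <- NULL

  monitored <- !const_par
  bad_rhat <- monitored & !is.na(rhat) & rhat > 1.1
  bad_ess <- monitored & !is.na(ess) & ess < 400
  converged <- !any(bad_rhat | bad_ess)
  if (!converged)
    warning("convergence concerns: ",
            paste(par_names[bad_rhat | bad_ess], collapse = ", "),
            " (R-hat > 1.1 or ESS < 400)")

  structure(list(draws = draws, summary = smry,
                 species_levels = data$species_levels,
                 evi_center = data$evi_center,
                 config = list(chains = chains, iter = iter, warmup = warmup,
                               seed = seed, mu_prior_sd = mu_prior_sd,
                               sigma_upper = sigma_upper,
                               hyper_fixed = hyper_fixed),
                 flags = list(converged = converged,
                              one_class_species = one_class,
                              n_obs = length(y),
                              n_missing = sum(!obs))),
            class = "yearling_fit")
}

#' @export
print.yearling_fit <- function(x, ...) {
  cat("Hierarchical yearling model fit:", length(x$species_levels),
      "species,", x$flags$n_obs, "observed +", x$flags$n_missing,
      "unknown-age individuals\n")
  cat(sprintf("%d chains x %d iterations (+%d warmup), converged: %s\n",
              x$config$chains, x$config$iter, x$config$warmup,
              x$flags$converged))
  hp <- x$summary[x$summary$parameter %in%
                    c("mu_alpha", "mu_beta", "sigma_alpha", "sigma_beta"), ]
  print(hp, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract the posterior draw matrix
#' @param fit `yearling_fit` object.
#' @return matrix (draws x parameters) pooling all chains.
#' @export
posterior_matrix <- function(fit) {
  do.call(rbind, lapply(fit$draws, as.matrix))
}

#' Yearling probability from species effects
#'
#' The inverse-logit curve of the fitted model: probability that an adult
#' captured at a (centered) EVI value is a yearling.
#'
#' @param alpha,beta species intercept and EVI coefficient.
#' @param evi centered EVI value(s).
#' @return probabilities in (0, 1).
#' @export
predict_yearling_prob <- function(alpha, beta, evi) {
  stopifnot(is.finite(alpha), is.finite(beta), all(is.finite(evi)))
  plogis(alpha + beta * evi)
}

#' Impute latent ages for unknown-age (AHY) adults
#'
#' Post-hoc reporting aid: for each AHY individual, draws a latent SY/ASY
#' age from its species' posterior yearling-probability curve at the
#' individual's covariate value, using the posterior mean effects. Under the
#' model these outcomes do not inform the fit; imputation is for
#' completeness of reporting only.
#'
#' @param fit `yearling_fit`.
#' @param data the `yearling_model_data` the fit used.
#' @param seed integer seed.
#' @return integer vector matching `data$y` with NAs replaced by draws.
#' @export
impute_unknown_ages <- function(fit, data, seed = 1) {
  set.seed(seed)
  sm <- fit$summary
  a <- sm$mean[match(paste0("alpha[", data$species_levels, "]"), sm$parameter)]
  b <- sm$mean[match(paste0("beta[", data$species_levels, "]"), sm$parameter)]
  y <- data$y
  miss <- which(is.na(y))
  p <- plogis(a[data$species_idx[miss]] + b[data$species_idx[miss]] *
                data$evi[miss])
  y[miss] <- rbinom(length(miss), 1L, p)
  y
}
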