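# small deterministic model-data object built by hand
toy_model_data <- function(y, evi, species_idx = rep(1L, length(y)),
                           levels = paste0("SP", sort(unique(species_idx)))) {
  structure(list(y = as.integer(y), species_idx = as.integer(species_idx),
                 species_levels = levels, evi = evi, evi_center = 0,
                 station_id = rep("ST01", length(y)),
                 year = rep(2012L, length(y)), n = length(y),
                 J = length(levels), n_dropped = 0L),
            class = "yearling_model_data")
}

test_that("build_model_data codes outcomes and centers the covariate", {
  inds <- data.frame(band_id = c("B1", "B2", "B3"),
                     species_code = "TEWA", station_id = c("S1", "S2", "S1"),
                     year = 2012L, resolved_age = c("SY", "ASY", "AHY"),
                     stringsAsFactors = FALSE)
  sev <- data.frame(station_id = c("S1", "S2"), year = 2012L,
                    evi = c(0.3, 0.6))
  md <- build_model_data(inds, sev)
  expect_equal(md$y, c(1L, 0L, NA_integer_))
  expect_lt(abs(mean(md$evi)), 1e-9)
  expect_equal(uncenter_covariate(structure(md$evi, center = md$evi_center)),
               c(0.3, 0.6, 0.3))
  # individuals without a covariate are dropped with a note
  sev2 <- sev[1, ]
  expect_message(md2 <- build_model_data(inds, sev2), "dropped 1")
  expect_equal(md2$n, 2L)
  # bookkeeping on generator output: rows = target-species bird-years
  sim <- simulate_study(tiny_config(), seed = 31)
  inds_g <- resolve_year_unique(sim$captures)
  sev_g <- station_year_evi(sim$evi$cells)
  md_g <- build_model_data(inds_g, sev_g)
  expect_equal(md_g$n + md_g$n_dropped, sim$truth$n_adult_bird_years)
})

test_that("log_unnormalized_posterior matches an independent scalar sum", {
  set.seed(55)
  n <- 10
  md <- toy_model_data(y = rbinom(n, 1, 0.5), evi = rnorm(n, 0, 0.3),
                       species_idx = sample(1:2, n, replace = TRUE),
                       levels = c("AAAA", "BBBB"))
  pars <- list(alpha = c(0.3, -0.2), beta = c(-1.1, 0.4),
               mu_alpha = 0.1, mu_beta = -0.5,
               sigma_alpha = 0.8, sigma_beta = 1.2)
  # brute force: scalar loop with explicit Bernoulli probabilities
  brute <- 0
  for (i in seq_len(n)) {
    p <- 1 / (1 + exp(-(pars$alpha[md$species_idx[i]] +
                          pars$beta[md$species_idx[i]] * md$evi[i])))
    brute <- brute + log(ifelse(md$y[i] == 1, p, 1 - p))
  }
  for (j in 1:2) {
    brute <- brute + dnorm(pars$alpha[j], pars$mu_alpha, pars$sigma_alpha,
                           log = TRUE) +
      dnorm(pars$beta[j], pars$mu_beta, pars$sigma_beta, log = TRUE)
  }
  brute <- brute + dnorm(pars$mu_alpha, 0, 10, log = TRUE) +
    dnorm(pars$mu_beta, 0, 10, log = TRUE) - 2 * log(10)
  expect_equal(log_unnormalized_posterior(md, pars), brute, tolerance = 1e-10)

  # missing outcomes contribute nothing
  md_na <- md
  md_na$y[3] <- NA_integer_
  drop3 <- toy_model_data(md$y[-3], md$evi[-3], md$species_idx[-3],
                          levels = md$species_levels)
  expect_equal(log_unnormalized_posterior(md_na, pars),
               log_unnormalized_posterior(drop3, pars))
  # out-of-support parameters give -Inf
  bad <- pars; bad$sigma_beta <- -1
  expect_identical(log_unnormalized_posterior(md, bad), -Inf)
  bad2 <- pars; bad2$alpha[1] <- NaN
  expect_identical(log_unnormalized_posterior(md, bad2), -Inf)
})

test_that("likelihood terms behave at reference points and limits", {
  md1 <- toy_model_data(1L, 0.7)
  flat <- list(alpha = 0, beta = 0, mu_alpha = 0, mu_beta = 0,
               sigma_alpha = 10, sigma_beta = 10)
  base <- log_unnormalized_posterior(md1, flat)
  # likelihood term at alpha = beta = 0 is log(0.5) regardless of evi
  md1b <- toy_model_data(1L, -2.4)
  expect_equal(log_unnormalized_posterior(md1b, flat), base)
  # alpha -> +inf drives the y = 1 likelihood term to 0 from below
  lik_term <- function(a) {
    p1 <- list(alpha = a, beta = 0, mu_alpha = 0, mu_beta = 0,
               sigma_alpha = 10, sigma_beta = 10)
    log_unnormalized_posterior(md1, p1) -
      (dnorm(a, 0, 10, log = TRUE) + dnorm(0, 0, 10, log = TRUE) +
         dnorm(0, 0, 10, log = TRUE) + dnorm(0, 0, 10, log = TRUE) -
         2 * log(10))
  }
  expect_equal(lik_term(0), log(0.5))
  expect_lt(lik_term(20), 0)
  expect_gt(lik_term(20), -1e-8)
})

test_that("predict_yearling_prob is the inverse logit", {
  expect_equal(predict_yearling_prob(0, 0, 1.7), 0.5)
  evi <- seq(-0.2, 0.2, length.out = 11)
  p <- predict_yearling_prob(0.4, -2, evi)
  expect_true(all(diff(p) < 0))
  set.seed(66)
  a <- rnorm(20); b <- rnorm(20); e <- rnorm(20)
  expect_equal(predict_yearling_prob(a, b, e), 1 / (1 + exp(-(a + b * e))),
               tolerance = 1e-12)
})

test_that("single-species posterior mode matches a brute-force grid search", {
  set.seed(12)
  n <- 30
  evi <- rnorm(n, 0, 0.5)
  y <- rbinom(n, 1, plogis(0.5 - 1 * evi))
  md <- toy_model_data(y, evi)
  fixed <- list(mu_alpha = 0, mu_beta = 0, sigma_alpha = 5, sigma_beta = 5)
  fit <- fit_yearling_model(md, chains = 2, iter = 4000, warmup = 1000,
                            seed = 2, hyper_fixed = fixed)
  # independent oracle: exhaustive evaluation on a lattice
  grid <- expand.grid(alpha = seq(-3, 3, by = 0.05),
                      beta = seq(-6, 6, by = 0.05))
  lp <- mapply(function(a, b) log_unnormalized_posterior(
    md, list(alpha = a, beta = b, mu_alpha = 0, mu_beta = 0,
             sigma_alpha = 5, sigma_beta = 5)), grid$alpha, grid$beta)
  mode_grid <- grid[which.max(lp), ]
  # MCMC mode: highest-posterior draw
  m <- posterior_matrix(fit)
  lp_draws <- apply(m, 1, function(r) log_unnormalized_posterior(
    md, list(alpha = r[1], beta = r[2], mu_alpha = 0, mu_beta = 0,
             sigma_alpha = 5, sigma_beta = 5)))
  mode_mcmc <- m[which.max(lp_draws), c(1, 2)]
  expect_lt(abs(mode_mcmc[1] - mode_grid$alpha), 0.1)
  expect_lt(abs(mode_mcmc[2] - mode_grid$beta), 0.1)
})

test_that("single-species posterior concentrates at the grid-search MLE", {
  set.seed(14)
  n <- 2000
  evi <- rnorm(n, 0, 0.5)
  y <- rbinom(n, 1, plogis(0.2 + 0.8 * evi))
  md <- toy_model_data(y, evi)
  fit <- fit_yearling_model(md, chains = 2, iter = 2000, warmup = 1000,
                            seed = 3,
                            hyper_fixed = list(mu_alpha = 0, mu_beta = 0,
                                               sigma_alpha = 10,
                                               sigma_beta = 10))
  # flat-prior MAP on a fine lattice is the logistic MLE
  ll <- function(a, b) sum(y * (a + b * evi) - log1p(exp(a + b * evi)))
  grid <- expand.grid(alpha = seq(-0.3, 0.7, by = 0.01),
                      beta = seq(0.2, 1.4, by = 0.01))
  mle <- grid[which.max(mapply(ll, grid$alpha, grid$beta)), ]
  sm <- fit$summary
  a_hat <- sm$mean[sm$parameter == "alpha[SP1]"]
  b_hat <- sm$mean[sm$parameter == "beta[SP1]"]
  a_sd <- sm$sd[sm$parameter == "alpha[SP1]"]
  b_sd <- sm$sd[sm$parameter == "beta[SP1]"]
  expect_lt(abs(a_hat - mle$alpha), 3 * a_sd + 0.01)
  expect_lt(abs(b_hat - mle$beta), 3 * b_sd + 0.01)
  expect_lt(a_sd, 0.1)     # concentration at n = 2000
  expect_lt(b_sd, 0.25)
})

test_that("AHY rows do not change the posterior (shared seed)", {
  sim <- simulate_study(tiny_config(mean_captures = 6), seed = 41)
  inds <- resolve_year_unique(sim$captures)
  sev <- station_year_evi(sim$evi$cells)
  md <- build_model_data(inds, sev)
  md_obs <- md
  keep <- !is.na(md$y)
  for (f in c("y", "species_idx", "evi", "station_id", "year"))
    md_obs[[f]] <- md[[f]][keep]
  md_obs$n <- sum(keep)
  f1 <- suppressWarnings(fit_yearling_model(md, chains = 1, iter = 300,
                                            warmup = 300, seed = 6))
  f2 <- suppressWarnings(fit_yearling_model(md_obs, chains = 1, iter = 300,
                                            warmup = 300, seed = 6))
  expect_identical(posterior_matrix(f1), posterior_matrix(f2))
})

test_that("sigma_beta pinned near zero pools all species slopes", {
  sim <- simulate_study(tiny_config(mean_captures = 6), seed = 43)
  inds <- resolve_year_unique(sim$captures)
  sev <- station_year_evi(sim$evi$cells)
  md <- build_model_data(inds, sev)
  fit <- suppressWarnings(fit_yearling_model(
    md, chains = 1, iter = 500, warmup = 500, seed = 9,
    hyper_fixed = list(sigma_beta = 1e-4)))
  m <- posterior_matrix(fit)
  betas <- m[, grep("^beta\\[", colnames(m)), drop = FALSE]
  mu <- m[, "mu_beta"]
  expect_lt(max(abs(betas - mu)), 0.01)
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  sim <- simulate_study(tiny_config(mean_captures = 8), seed = 47)
  inds <- resolve_year_unique(sim$captures)
  sev <- station_year_evi(sim$evi$cells)
  md <- build_model_data(inds, sev)
  fit <- suppressWarnings(fit_yearling_model(md, chains = 2, iter = 1500,
                                             warmup = 1000, seed = 4))
  obs <- !is.na(md$y)
  dat <- list(y = md$y[obs], sp = md$species_idx[obs], evi = md$evi[obs],
              N = sum(obs), J = md$J)
  mtxt <- "model{
    for (i in 1:N) { y[i] ~ dbern(ilogit(alpha[sp[i]] + beta[sp[i]] * evi[i])) }
    for (j in 1:J) { alpha[j] ~ dnorm(mu_a, pow(sg_a, -2))
                     beta[j] ~ dnorm(mu_b, pow(sg_b, -2)) }
    mu_a ~ dnorm(0, 0.01); mu_b ~ dnorm(0, 0.01)
    sg_a ~ dunif(0, 10); sg_b ~ dunif(0, 10)
  }"
  jm <- rjags::jags.model(textConnection(mtxt), data = dat, n.chains = 2,
                          n.adapt = 500, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 11))
  update(jm, 500, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("mu_a", "mu_b", "sg_a", "sg_b"),
                            n.iter = 2000, progress.bar = "none")
  jstat <- summary(js)$statistics
  sm <- fit$summary
  for (pair in list(c("mu_alpha", "mu_a"), c("mu_beta", "mu_b"),
                    c("sigma_alpha", "sg_a"))) {
    ours <- sm[sm$parameter == pair[1], ]
    se <- sqrt(ours$sd^2 + jstat[pair[2], "SD"]^2)
    expect_lt(abs(ours$mean - jstat[pair[2], "Mean"]), se,
              label = paste(pair[1], "difference vs JAGS"))
  }
})

test_that("species_evi_profiles computes capture-weighted means and groups", {
  inds <- data.frame(
    band_id = sprintf("B%02d", 1:6),
    species_code = c("AAAA", "AAAA", "BBBB", "CCCC", "CCCC", "DDDD"),
    station_id = c("S1", "S2", "S1", "S2", "S2", "S2"),
    year = 2012L,
    resolved_age = c("SY", "ASY", "SY", "ASY", "SY", "AHY"),
    stringsAsFactors = FALSE)
  sev <- data.frame(station_id = c("S1", "S2"), year = 2012L,
                    evi = c(0.2, 0.6))
  pr <- species_evi_profiles(inds, sev)
  expect_equal(pr$evi_mean[pr$species_code == "AAAA"], 0.4)
  expect_equal(pr$evi_range[pr$species_code == "AAAA"], 0.4)
  # all captures at one station-year: mean is that EVI, range 0
  expect_equal(pr$evi_mean[pr$species_code == "CCCC"], 0.6)
  expect_equal(pr$evi_range[pr$species_code == "CCCC"], 0)

  # quartile grouping: means 1,2,3,4 split 1 / 2,3 / 4
  g <- assign_habitat_groups(c(1, 2, 3, 4))
  expect_equal(as.character(g),
               c("successional", "intermediate", "intermediate", "mature"))
  # 29 species: group sizes match an independent quantile computation
  set.seed(91)
  means <- rnorm(29)
  g29 <- assign_habitat_groups(means)
  q <- quantile(means, c(0.25, 0.75))
  expect_equal(sum(g29 == "successional"), sum(means <= q[1]))
  expect_equal(sum(g29 == "mature"), sum(means > q[2]))
  expect_equal(sum(g29 == "intermediate"),
               sum(means > q[1] & means <= q[2]))
})

test_that("group_coefficient_summary averages betas within groups per draw", {
  sim <- simulate_study(tiny_config(), seed = 51)
  inds <- resolve_year_unique(sim$captures)
  sev <- station_year_evi(sim$evi$cells)
  md <- build_model_data(inds, sev)
  fit <- suppressWarnings(fit_yearling_model(md, chains = 1, iter = 200,
                                             warmup = 200, seed = 5))
  pr <- species_evi_profiles(inds, sev)
  gs <- group_coefficient_summary(fit, pr)
  expect_equal(as.character(gs$habitat_group),
               c("successional", "intermediate", "mature"))
  expect_true(all(gs$q2.5 <= gs$mean & gs$mean <= gs$q97.5, na.rm = TRUE))
  expect_equal(sum(gs$n_species), md$J)
  # permuting species order leaves the summaries unchanged
  perm <- sample(nrow(pr))
  gs2 <- group_coefficient_summary(fit, pr[perm, ])
  expect_equal(gs, gs2)
  # independent check: per-draw group means recomputed directly
  m <- posterior_matrix(fit)
  grp <- pr$habitat_group[match(fit$species_levels, pr$species_code)]
  for (g in levels(grp)) {
    cols <- paste0("beta[", fit$species_levels[grp == g], "]")
    if (!length(cols)) next
    gm <- rowMeans(m[, cols, drop = FALSE])
    expect_equal(gs$mean[gs$habitat_group == g], mean(gm))
  }
})

test_that("coefficient_meta_regression recovers structured coefficients", {
  set.seed(61)
  J <- 40
  prof <- data.frame(species_code = make_species_codes(J),
                     evi_mean = runif(J, 0.3, 0.6),
                     evi_range = runif(J, 0.05, 0.3),
                     n_captures = 50L,
                     habitat_group = factor("intermediate",
                                            c("successional", "intermediate",
                                              "mature")))
  z <- function(v) (v - mean(v)) / sd(v)
  beta <- -0.7 * z(prof$evi_mean) + 0.1 * z(prof$evi_range) +
    rnorm(J, 0, 0.2)
  fit <- coefficient_meta_regression(beta, prof)
  cf <- fit$coefficients
  em <- cf[cf$term == "evi_mean", ]
  er <- cf[cf$term == "evi_range", ]
  expect_true(em$ci_lower < -0.7 && -0.7 < em$ci_upper)
  expect_true(er$ci_lower < 0.1 && 0.1 < er$ci_upper)
  # zero noise: perfect fit
  beta0 <- -0.7 * z(prof$evi_mean) + 0.1 * z(prof$evi_range)
  expect_equal(suppressWarnings(coefficient_meta_regression(beta0, prof))$r_squared, 1)
  # null: independent responses, CIs cover zero (large J)
  set.seed(62)
  J2 <- 200
  prof2 <- data.frame(species_code = make_species_codes(J2),
                      evi_mean = runif(J2, 0.3, 0.6),
                      evi_range = runif(J2, 0.05, 0.3))
  cf2 <- coefficient_meta_regression(rnorm(J2), prof2)$coefficients
  for (tm in c("evi_mean", "evi_range")) {
    row <- cf2[cf2$term == tm, ]
    expect_true(row$ci_lower < 0 && 0 < row$ci_upper, info = tm)
  }
  expect_error(coefficient_meta_regression(rnorm(3), prof2[1:3, ]),
               "at least 4")
})
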