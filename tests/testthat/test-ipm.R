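test_that("mcmc configurations enforce their invariants", {
  desk <- mcmc_config("desk")
  expect_equal(desk$n_chains * (desk$n_iterations - desk$n_burnin) %/%
                 desk$thin, 4500)
  study <- mcmc_config("study")
  expect_equal(study$n_iterations - study$n_burnin, 160000)
  expect_equal(study$thin, 10)
  expect_error(mcmc_config(n_chains = 3, n_iterations = 100, n_burnin = 100,
                           thin = 1), "n_iterations > n_burnin")
  expect_error(mcmc_config(n_chains = 3, n_iterations = 100, n_burnin = 10,
                           thin = 0), "thin")
})

test_that("joint density decomposes additively across components", {
  sim <- simulate_ipm_data(n_years = 6, releases_per_year = 8, seed = 20)
  hyper <- sim$hyper
  jd <- joint_log_density(sim$rates, sim$abundance, hyper, sim$histories,
                          sim$census, split = sim$split)
  expect_equal(jd$total, jd$cmr + jd$state_space + jd$prior, tolerance = 1e-10)
  # cross-module check: components equal the module-level functions
  expect_equal(jd$cmr, total_cmr_loglik(sim$histories, sim$rates))
  expect_equal(jd$state_space,
               state_space_logdensity(sim$abundance, sim$census, sim$rates,
                                      split = sim$split)$total)
  # empty capture-history set: only state-space and prior terms remain
  jd0 <- joint_log_density(sim$rates, sim$abundance, hyper, NULL,
                           sim$census, split = sim$split)
  expect_equal(jd0$cmr, 0)
  expect_equal(jd0$total, jd$total - jd$cmr)
  # doubling every history changes exactly the CMR term, by its own value
  dbl <- capture_histories(rbind(sim$histories$obs, sim$histories$obs),
                           years = sim$histories$years)
  jd2 <- joint_log_density(sim$rates, sim$abundance, hyper, dbl,
                           sim$census, split = sim$split)
  expect_equal(jd2$cmr, 2 * jd$cmr, tolerance = 1e-10)
  expect_equal(jd2$total - jd$total, jd$cmr, tolerance = 1e-10)
})

test_that("gelman-rubin behaves analytically at its edges", {
  x <- rep(1:50, 2)
  two_identical <- cbind(chain1 = x, chain2 = x)
  expect_lte(gelman_rubin(two_identical), 1)
  # chains offset by five within-chain SDs inflate the statistic
  set.seed(30)
  a <- rnorm(1000)
  offset <- cbind(a, a + 5 * sd(a))
  expect_gt(gelman_rubin(offset), 1.5)
  # iid draws from a common distribution converge to 1
  clean <- matrix(rnorm(6000), 2000, 3)
  expect_lt(gelman_rubin(clean), 1.05)
  expect_error(gelman_rubin(matrix(rnorm(10), 10, 1)), "2 chains")
})

test_that("fits are deterministic given the seed and validate inputs", {
  sim <- simulate_ipm_data(n_years = 6, releases_per_year = 8, seed = 22)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 300, n_burnin = 100,
                     thin = 2)
  f1 <- suppressWarnings(fit_ipm(sim$histories, sim$census, cfg, seed = 5))
  f2 <- suppressWarnings(fit_ipm(sim$histories, sim$census, cfg, seed = 5))
  expect_identical(f1$draws$rates, f2$draws$rates)
  expect_identical(f1$draws$latent, f2$draws$latent)
  f3 <- suppressWarnings(fit_ipm(sim$histories, sim$census, cfg, seed = 6))
  expect_false(identical(f1$draws$rates, f3$draws$rates))
  expect_equal(dim(f1$draws$hyper), c(2 * 100, 20))
  short <- sim$census[1:3, ]
  expect_error(fit_ipm(sim$histories, short, cfg), "5 years")
  expect_error(fit_ipm(sim$histories, sim$census[, 1:2], cfg), "columns")
})

test_that("a desk-scale fit recovers the generating conditions", {
  sim <- simulate_ipm_data(n_years = 14, releases_per_year = 30, seed = 23)
  fit <- suppressWarnings(fit_ipm(sim$histories, sim$census,
                                  mcmc_config("desk"), seed = 2))
  expect_s3_class(fit, "ipm_fit")
  # posterior abundance tracks the simulated truth within 3 posterior SDs
  T_yrs <- length(fit$years)
  for (t in c(5, 10, T_yrs)) {
    tot_draws <- fit$draws$latent[, "N_ad", t] + fit$draws$latent[, "N_imm", t]
    truth <- sim$abundance$N_ad[t] + sim$abundance$N_imm[t]
    expect_lt(abs(mean(tot_draws) - truth), 3 * max(sd(tot_draws), 1))
  }
  # hyper-mean point estimates land in sane demographic ranges
  est <- coef(fit)
  expect_true(est["phi_ad_W"] > 0.6 && est["phi_ad_W"] < 0.95)
  expect_true(est["omega"] > 0.02 && est["omega"] < 0.5)
  # summary table carries all scalars with valid interval ordering
  s <- summarize_posterior(fit)
  expect_true(all(s$lower <= s$mean + 1e-9 & s$mean <= s$upper + 1e-9))
  expect_true(all(c("hypermean[phi_ad_W]", "mu[omega]", "N_ad[1996]",
                    "phi_juv_W[1983]") %in% s$parameter))
  # gelman_rubin resolves named scalars from the fit
  expect_true(is.finite(gelman_rubin(fit, "mu[phi_ad_W]")))
  expect_true(is.finite(gelman_rubin(fit, "N_ad[1990]")))
  expect_error(gelman_rubin(fit, "nonsense[1]"), "unknown parameter")
})

test_that("posterior summaries behave on degenerate and simulated draws", {
  # constant draws: zero-width interval at the constant
  x <- matrix(5, 100, 2)
  expect_equal(gelman_rubin(x), 1)
  sim <- simulate_ipm_data(n_years = 6, releases_per_year = 8, seed = 27)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 200, n_burnin = 100,
                     thin = 1)
  fit <- suppressWarnings(fit_ipm(sim$histories, sim$census, cfg, seed = 3))
  s <- summarize_posterior(fit, which = "hyper")
  expect_equal(nrow(s), 20 + 10)  # mu, sigma, natural-scale hypermeans
  # 95% interval of standard normal draws ~ (-1.96, 1.96)
  set.seed(40)
  z <- rnorm(1e5)
  expect_equal(unname(quantile(z, c(.025, .975))), c(-1.96, 1.96),
               tolerance = 0.03)
})

test_that("posterior predictive census simulation is seed-stable", {
  sim <- simulate_ipm_data(n_years = 6, releases_per_year = 8, seed = 24)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 200, n_burnin = 100,
                     thin = 1)
  fit <- suppressWarnings(fit_ipm(sim$histories, sim$census, cfg, seed = 4))
  pp1 <- simulate(fit, nsim = 3, seed = 9)
  pp2 <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(pp1, pp2)
  expect_length(pp1, 3)
  expect_named(pp1[[1]], c("year", "A", "J"))
})
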