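test_that("transition and emission rows are proper distributions", {
  rates <- draw_annual_rates(default_hyperparams(), 6, seed = 9)
  for (t in 1:6) {
    m <- build_transition_and_emission(rates[t, ])
    expect_equal(unname(rowSums(m$transition)), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(rowSums(m$emission)), rep(1, 4), tolerance = 1e-12)
    # death absorbing and unobservable
    expect_equal(unname(m$transition[4, ]), c(0, 0, 0, 1))
    expect_equal(unname(m$emission[4, ]), c(1, 0, 0))
  }
  expect_error(transition_matrix(list(phi_juv_W = 1.4)), "rate")
})

test_that("juvenile transition row matches the survival-movement product", {
  P <- transition_matrix(reported_rates(1)[1, ])
  expect_equal(unname(P[1, ]), c(0, 0.70 * 0.84, 0.70 * 0.16, 0.30),
               tolerance = 1e-12)
})

test_that("hand-enumerated history probabilities are reproduced", {
  rates <- reported_rates(1)
  # released, never seen again: dead, or alive-undetected at W or E
  p_unseen <- (1 - 0.70) + 0.70 * (0.84 * (1 - 0.86) + 0.16 * (1 - 0.60))
  expect_equal(capture_history_loglik(c(1, 0), rates), log(p_unseen),
               tolerance = 1e-12)
  expect_equal(log(p_unseen), -0.8507, tolerance = 1e-4)
  # certain survival, fidelity and detection: probability one
  sure <- reported_rates(3, phi_juv_W = 1, phi_ad_W = 1, psi_juv_WE = 0,
                         psi_ad_WE = 0, p_W = 1)
  expect_equal(capture_history_loglik(c(1, 1, 1, 1), sure), 0)
  # death before any resighting chance: later sighting impossible
  dead <- reported_rates(2, phi_juv_W = 0)
  expect_equal(capture_history_loglik(c(1, 0, 1), dead), -Inf)
})

test_that("infeasible histories are rejected with informative errors", {
  rates <- reported_rates(3)
  expect_error(capture_history_loglik(c(2, 0, 0, 0), rates), "release")
  expect_error(capture_history_loglik(c(0, 0, 0, 0), rates), "no sightings")
  expect_error(capture_history_loglik(c(1, 0, 3, 0), rates), "codes")
})

test_that("forward recursion equals brute-force path enumeration", {
  # the central correctness check: marginal likelihood vs exact sum over
  # all latent state paths, on many random short histories
  set.seed(31)
  h <- default_hyperparams()
  for (k in 1:200) {
    T_occ <- sample(2:6, 1)
    rates <- draw_annual_rates(h, max(T_occ - 1, 2))[seq_len(T_occ - 1), ]
    release <- sample.int(T_occ - 1, 1)
    hist <- integer(T_occ)
    hist[release] <- 1L
    if (release < T_occ) {
      m <- T_occ - release
      hist[(release + 1):T_occ] <- sample(0:2, m, replace = TRUE)
    }
    expect_equal(capture_history_loglik(hist, rates, release),
                 capture_history_loglik_bruteforce(hist, rates, release),
                 tolerance = 1e-10)
  }
})

test_that("oracle probabilities over all observation suffixes sum to one", {
  # law of total probability over the 3^(T-1) possible post-release codes
  rates <- draw_annual_rates(default_hyperparams(), 3, seed = 77)
  suffixes <- expand.grid(rep(list(0:2), 3))
  total <- sum(apply(suffixes, 1, function(sfx) {
    h <- c(1L, as.integer(sfx))
    exp(capture_history_loglik_bruteforce(h, rates, release = 1))
  }))
  expect_equal(total, 1, tolerance = 1e-10)
  expect_error(
    capture_history_loglik_bruteforce(c(1L, integer(11)),
                                      draw_annual_rates(default_hyperparams(), 11),
                                      max_occasions = 8),
    "enumeration")
})

test_that("set log-likelihood is additive over histories", {
  rates <- reported_rates(4)
  sim <- simulate_capture_histories(rates, releases_per_year = 8, seed = 14)
  per_hist <- vapply(seq_len(nrow(sim$obs)), function(i)
    capture_history_loglik(sim$obs[i, ], rates, sim$release[i]), 0)
  expect_equal(total_cmr_loglik(sim, rates), sum(per_hist), tolerance = 1e-10)
  # duplicating one history adds exactly its contribution
  dup <- capture_histories(sim$obs[c(seq_len(nrow(sim$obs)), 1), ],
                           years = sim$years)
  expect_equal(total_cmr_loglik(dup, rates),
               total_cmr_loglik(sim, rates) + per_hist[1], tolerance = 1e-10)
  expect_equal(total_cmr_loglik(NULL, rates), 0)
})

test_that("likelihood maximum recovers the generating rates", {
  # grid/optimizer maximum over (phi_juv_W, p_W) on a large simulated set
  truth <- reported_means()
  rates <- constant_rates(truth, 2)
  sim <- simulate_capture_histories(rates, releases_per_year = 2500, seed = 6)
  nll <- function(par) {
    r <- truth
    r["phi_juv_W"] <- plogis(par[1])
    r["p_W"] <- plogis(par[2])
    -total_cmr_loglik(sim, constant_rates(r, 2))
  }
  opt <- optim(qlogis(c(0.5, 0.5)), nll)
  est <- plogis(opt$par)
  # binomial-scale standard errors at n = 5000 releases
  n <- nrow(sim$obs)
  expect_lt(abs(est[1] - 0.70), 3 * sqrt(0.7 * 0.3 / n) / 0.84)
  expect_lt(abs(est[2] - 0.86), 3 * sqrt(0.86 * 0.14 / (n * 0.5)))
})
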