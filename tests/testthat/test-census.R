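test_that("step expectations follow the printed process equations", {
  r <- reported_rates(1)[1, ]
  expect_equal(step_expectations(c(N_juv = 0, N_ad = 0, N_imm = 0), r),
               c(N_juv = 0, N_ad = 0, N_imm = 0))
  e <- step_expectations(c(N_juv = 0, N_ad = 4000, N_imm = 0), r)
  expect_equal(unname(e["N_juv"]), 0.16 * 4000)   # beta * N_ad = 640
  e2 <- step_expectations(c(N_juv = 600, N_ad = 4000, N_imm = 680), r)
  expect_equal(unname(e2["N_ad"]),
               600 * 0.70 * 0.84 + 4680 * 0.81 * 0.91, tolerance = 1e-12)
  expect_equal(unname(e2["N_ad"]), 3802.4, tolerance = 1e-3)
  expect_equal(unname(e2["N_imm"]), 5280 * 0.17, tolerance = 1e-12)
  expect_error(step_expectations(c(N_juv = -1, N_ad = 0, N_imm = 0), r),
               "nonnegative")
})

make_path <- function(n_years, seed = 1) {
  rates <- reported_rates(n_years)
  sim <- simulate_population(rates, seed = seed)
  list(rates = rates, latent = sim$abundance, census = sim$census,
       split = sim$split)
}

test_that("state-space density decomposes additively and reproducibly", {
  p <- make_path(6)
  d <- state_space_logdensity(p$latent, p$census, p$rates, split = p$split)
  expect_s3_class(d, "ss_density")
  expect_equal(d$total,
               sum(d$process$juv, d$process$ad, d$process$imm,
                   d$observation$J, d$observation$A),
               tolerance = 1e-10)
  expect_true(is.finite(d$total))
  # independent recomputation of two representative terms
  expect_equal(d$process$juv[3],
               dpois(p$latent$N_juv[3], 0.16 * p$latent$N_ad[2], log = TRUE))
  expect_equal(d$observation$J[4],
               dpois(p$census$J[4], p$latent$N_juv[4], log = TRUE))
})

test_that("adult survivor binomial term matches the hand value", {
  # 3 survivors from a pool of 5 at success 0.81 * 0.91
  lat <- data.frame(year = 1:2, N_juv = c(0, 0), N_ad = c(5, 3),
                    N_imm = c(0, 0))
  cen <- data.frame(year = 1:2, A = c(5, 3), J = c(0, 0))
  rates <- reported_rates(1, beta = 0, omega = 0)
  rates$year <- 1
  d <- state_space_logdensity(lat, cen, rates, split = 0L)
  expect_equal(d$process$ad[2], log(choose(5, 3) * 0.7371^3 * 0.2629^2),
               tolerance = 1e-6)
  expect_equal(d$process$ad[2], -1.284, tolerance = 1e-3)
})

test_that("impossible adult transitions yield a -Inf sentinel", {
  lat <- data.frame(year = 1:2, N_juv = c(10, 0), N_ad = c(20, 100),
                    N_imm = c(0, 0))
  cen <- data.frame(year = 1:2, A = c(20, 100), J = c(10, 0))
  rates <- reported_rates(1); rates$year <- 1
  d <- state_space_logdensity(lat, cen, rates)   # marginalized split
  expect_identical(d$process$ad[2], -Inf)
  expect_identical(d$total, -Inf)
})

test_that("observation terms normalize over the count support", {
  # summing exp(observation term) over all feasible J values equals 1
  lat <- data.frame(year = 1:2, N_juv = c(40, 35), N_ad = c(100, 80),
                    N_imm = c(0, 5))
  rates <- reported_rates(1); rates$year <- 1
  total <- sum(vapply(0:200, function(j) {
    cen <- data.frame(year = 1:2, A = c(100, 85), J = c(j, 35))
    d <- state_space_logdensity(lat, cen, rates, split = 20L)
    exp(d$observation$J[1])
  }, 0))
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("marginalized split agrees with direct convolution", {
  p <- make_path(5, seed = 7)
  d_marg <- state_space_logdensity(p$latent, p$census, p$rates)
  # term-by-term convolution computed independently
  for (t in 1:4) {
    qj <- p$rates$phi_juv_W[t] * (1 - p$rates$psi_juv_WE[t])
    qa <- p$rates$phi_ad_W[t] * (1 - p$rates$psi_ad_WE[t])
    pool <- p$latent$N_ad[t] + p$latent$N_imm[t]
    s <- 0:p$latent$N_juv[t]
    direct <- log(sum(dbinom(s, p$latent$N_juv[t], qj) *
                        dbinom(p$latent$N_ad[t + 1] - s, pool, qa)))
    expect_equal(d_marg$process$ad[t + 1], direct, tolerance = 1e-10)
  }
})

test_that("density peaks near the expected adult count", {
  # over the latent adult count, the density maximum sits within 1 of the
  # process expectation for a smooth toy configuration
  rates <- reported_rates(1); rates$year <- 1
  e <- step_expectations(c(N_juv = 200, N_ad = 1000, N_imm = 0), rates[1, ])
  imm2 <- round(unname(e["N_imm"]))
  A2 <- round(unname(e["N_ad"])) + imm2
  vals <- vapply(round(e["N_ad"]) + (-30:30), function(na) {
    lat <- data.frame(year = 1:2, N_juv = c(200, 160), N_ad = c(1000, na),
                      N_imm = c(0, imm2))
    cen <- data.frame(year = 1:2, A = c(1000, A2), J = c(200, 160))
    state_space_logdensity(lat, cen, rates)$total
  }, 0)
  best <- (round(e["N_ad"]) + (-30:30))[which.max(vals)]
  expect_lte(abs(best - e["N_ad"]), 1 + 1)
})
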