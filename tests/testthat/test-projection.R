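test_that("projection matrices implement the three scenarios", {
  m <- reported_means()
  full <- projection_matrix(m, "full")
  expect_equal(unname(full["juv", ]), c(0, 0.16))
  expect_equal(unname(full["ad", "juv"]), 0.70 * 0.84 + 0.17,
               tolerance = 1e-12)                       # 0.758
  expect_equal(unname(full["ad", "ad"]), 0.81 * 0.91 + 0.17,
               tolerance = 1e-12)                       # 0.9071
  no_imm <- projection_matrix(m, "no_immigration")
  expect_equal(unname(no_imm["ad", ]), c(0.588, 0.7371), tolerance = 1e-12)
  no_mig <- projection_matrix(m, "no_migration")
  expect_equal(unname(no_mig["ad", ]), c(0.70, 0.81), tolerance = 1e-12)
  expect_equal(unname(no_mig["juv", "ad"]), 0.16)
  expect_error(projection_matrix(m, "everything"), "arg")
  expect_error(projection_matrix(m[-1]), "missing")
})

test_that("dominant eigenvalue matches hand-derived values", {
  expect_equal(lambda_dominant(matrix(c(0, 0, 0, 0.81), 2)), 0.81)
  m <- reported_means()
  expect_equal(lambda_dominant(projection_matrix(m, "full")), 1.025,
               tolerance = 1e-3)
  expect_equal(lambda_dominant(projection_matrix(m, "no_migration")), 0.930,
               tolerance = 1e-3)
})

test_that("closed-form and numeric eigenvalues agree to 1e-12", {
  set.seed(19)
  for (k in 1:200) {
    a <- matrix(c(0, runif(3, 0, 2)), 2)
    expect_equal(lambda_dominant(a, "eigen"), lambda_dominant(a, "closed"),
                 tolerance = 1e-12)
  }
})

test_that("lambda is monotone in every matrix entry", {
  m <- projection_matrix(reported_means(), "full")
  base <- lambda_dominant(m)
  for (i in 1:2) for (j in 1:2) {
    up <- m
    up[i, j] <- up[i, j] + 0.05
    expect_gte(lambda_dominant(unclass(up)), base)
  }
})

test_that("scenario lambdas order draw-wise and handle degeneracy", {
  set.seed(8)
  nd <- 60
  rd <- cbind(phi_juv_W = runif(nd, .5, .9), phi_ad_W = runif(nd, .6, .95),
              phi_ad_E = runif(nd, .5, .9), psi_juv_WE = runif(nd, 0, .4),
              psi_ad_WE = runif(nd, 0, .3), psi_ad_EW = runif(nd, 0, .4),
              p_W = runif(nd, .5, 1), p_E = runif(nd, .3, .9),
              beta = runif(nd, 0, .5), omega = runif(nd, 0, .4))
  draws <- fake_draws(rd)
  lam_full <- scenario_lambdas(draws, "full")
  lam_ni <- scenario_lambdas(draws, "no_immigration")
  lam_nm <- scenario_lambdas(draws, "no_migration")
  expect_true(all(lam_full$draws >= lam_ni$draws - 1e-12))
  expect_true(all(lam_nm$draws >= lam_ni$draws - 1e-12))
  # degenerate posterior collapses to the plug-in value
  one <- fake_draws(rd[rep(1, 10), ])
  lam1 <- scenario_lambdas(one, "full")
  expect_equal(unname(diff(lam1$cri)), 0)
  expect_equal(lam1$mean,
               lambda_dominant(projection_matrix(rd[1, ], "full")),
               tolerance = 1e-12)
  # beta = 0: triangular matrix, lambda = phi_ad_W (1 - psi_ad_WE) + omega
  rd0 <- rd; rd0[, "beta"] <- 0
  lam0 <- scenario_lambdas(fake_draws(rd0), "full")
  expect_equal(lam0$draws,
               unname(rd0[, "phi_ad_W"] * (1 - rd0[, "psi_ad_WE"]) +
                        rd0[, "omega"]),
               tolerance = 1e-12)
})

test_that("hyper-mean reduction uses the draw hyperparameters", {
  rd <- matrix(rep(reported_means(), each = 5), 5,
               dimnames = list(NULL, names(reported_means())))
  draws <- fake_draws(rd)
  mu <- reported_means()
  lg <- !(names(mu) %in% c("beta", "omega"))
  link <- ifelse(lg, qlogis(mu), log(mu))
  draws$hyper <- matrix(rep(link, each = 5), 5,
                        dimnames = list(NULL, paste0("mu[", names(mu), "]")))
  lam <- scenario_lambdas(draws, "full", rate_reduction = "hyper-mean")
  expect_equal(lam$mean,
               lambda_dominant(projection_matrix(reported_means(), "full")),
               tolerance = 1e-12)
})

test_that("source-sink classification follows the decision rule", {
  m <- reported_means()
  nd <- 50
  rd <- matrix(rep(m, each = nd), nd, dimnames = list(NULL, names(m)))
  # internal decline (lambda_no_migration ~ 0.93 < 1) + immigrant surplus
  lat <- array(0L, c(nd, 3, 5),
               dimnames = list(NULL, c("N_juv", "N_ad", "N_imm"), 1983:1987))
  lat[, "N_juv", ] <- 500L; lat[, "N_ad", ] <- 3000L; lat[, "N_imm", ] <- 600L
  sink_draws <- fake_draws(rd, n_years = 4, latent = lat)
  v <- classify_source_sink(sink_draws)
  expect_s3_class(v, "source_sink_verdict")
  expect_equal(v$label, "sink")
  expect_gt(v$mean_inflow, v$mean_outflow)
  # net growth without migration + emigration surplus: source
  m2 <- m; m2["phi_ad_W"] <- 0.95; m2["beta"] <- 0.40; m2["omega"] <- 0
  rd2 <- matrix(rep(m2, each = nd), nd, dimnames = list(NULL, names(m2)))
  lat2 <- lat; lat2[, "N_imm", ] <- 0L
  v2 <- classify_source_sink(fake_draws(rd2, n_years = 4, latent = lat2))
  expect_equal(v2$label, "source")
  # lambda straddling one: indeterminate
  set.seed(3)
  rd3 <- rd2[1:40, ]
  rd3[, "phi_ad_W"] <- runif(40, 0.7, 0.95)
  rd3[, "beta"] <- runif(40, 0.1, 0.45)
  v3 <- classify_source_sink(fake_draws(rd3, n_years = 4,
                                        latent = lat2[1:40, , ]))
  expect_equal(v3$label, "indeterminate")
})
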