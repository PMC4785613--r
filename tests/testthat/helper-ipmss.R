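# Shared fixtures for the test suite.

# Reported posterior-mean demographic rates (natural scale); the reference
# parameter point used throughout the tests.
reported_means <- function() {
  c(phi_juv_W = 0.70, phi_ad_W = 0.81, phi_ad_E = 0.79,
    psi_juv_WE = 0.16, psi_ad_WE = 0.09, psi_ad_EW = 0.20,
    p_W = 0.86, p_E = 0.60, beta = 0.16, omega = 0.17)
}

# constant annual-rates table at the reported means
reported_rates <- function(n_years = 5, ...) {
  r <- reported_means()
  ov <- list(...)
  r[names(ov)] <- unlist(ov)
  constant_rates(r, n_years)
}

# hyperparameters with all year-effect SDs zero at given natural-scale means
degenerate_hyper <- function(means = reported_means()) {
  mu <- means
  lg <- names(mu) %in% c("phi_juv_W", "phi_ad_W", "phi_ad_E", "psi_juv_WE",
                         "psi_ad_WE", "psi_ad_EW", "p_W", "p_E")
  mu[lg] <- qlogis(mu[lg])
  mu[!lg] <- log(mu[!lg])
  hyperparams(mu, setNames(rep(0, 10), names(mu)))
}

# a small synthetic draws object (as carried by ipm_fit) built from explicit
# per-draw rate vectors; latent abundances optional
fake_draws <- function(rate_draws, n_years = 4, latent = NULL) {
  nd <- nrow(rate_draws)
  rates <- array(NA_real_, c(nd, ncol(rate_draws), n_years),
                 dimnames = list(NULL, colnames(rate_draws),
                                 seq_len(n_years) + 1982))
  for (t in seq_len(n_years)) rates[, , t] <- rate_draws
  if (is.null(latent)) {
    latent <- array(100L, c(nd, 3, n_years + 1),
                    dimnames = list(NULL, c("N_juv", "N_ad", "N_imm"),
                                    seq_len(n_years + 1) + 1982))
  }
  list(rates = rates, latent = latent,
       hyper = matrix(0, nd, 0), chain = rep(1L, nd),
       iter = seq_len(nd))
}
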