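#' MCMC configuration
#'
#' Two named presets are provided: `"desk"` (3 chains of 4000 iterations,
#' 1000 burn-in, thinning 2 — minutes on a laptop, used throughout the tests)
#' and `"study"` (3 chains, 160 000 post-burn-in iterations after a burn-in of
#' 40 000, thinning 10 — the full-scale analysis setting).
#'
#' @param preset `"desk"` or `"study"`; ignored when the explicit arguments
#'   are all supplied.
#' @param n_chains number of chains (`>= 2` for convergence diagnostics).
#' @param n_iterations total iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations (`< n_iterations`).
#' @param thin thinning interval (`>= 1`).
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(preset = c("desk", "study"), n_chains = NULL,
                        n_iterations = NULL, n_burnin = NULL, thin = NULL) {
  if (is.null(n_chains) || is.null(n_iterations) || is.null(n_burnin) ||
      is.null(thin)) {
    preset <- match.arg(preset)
    def <- switch(preset,
                  desk = list(n_chains = 3L, n_iterations = 4000L,
                              n_burnin = 1000L, thin = 2L),
                  study = list(n_chains = 3L, n_iterations = 200000L,
                               n_burnin = 40000L, thin = 10L))
    if (is.null(n_chains)) n_chains <- def$n_chains
    if (is.null(n_iterations)) n_iterations <- def$n_iterations
    if (is.null(n_burnin)) n_burnin <- def$n_burnin
    if (is.null(thin)) thin <- def$thin
  } else preset <- "custom"
  if (n_burnin < 0 || n_iterations <= n_burnin)
    stop("need n_iterations > n_burnin >= 0")
  if (thin < 1) stop("thin must be >= 1")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(preset = preset, n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf("MCMC config [%s]: %d chains x %d iterations (burn-in %d, thin %d) -> %d draws\n",
              x$preset, x$n_chains, x$n_iterations, x$n_burnin, x$thin,
              x$n_chains * (x$n_iterations - x$n_burnin) %/% x$thin))
  invisible(x)
}

#' Prior configuration for the joint model
#'
#' Noninformative defaults: link-scale hyper-means `~ Normal(0, sd 10)`,
#' year-effect standard deviations `~ Uniform(0, 10)`, first-year latent
#' abundances discrete-uniform within +/- 50% of the first observed counts.
#'
#' @param mu_sd standard deviation of the Normal prior on link-scale means.
#' @param sigma_upper upper bound of the Uniform prior on year-effect SDs.
#' @param init_width half-width (fraction) of the first-year discrete-uniform
#'   abundance priors.
#' @return an object of class `ipm_priors`.
#' @export
ipm_priors <- function(mu_sd = 10, sigma_upper = 10, init_width = 0.5) {
  if (mu_sd <= 0 || sigma_upper <= 0 || init_width <= 0)
    stop("prior scales must be positive")
  structure(list(mu_sd = mu_sd, sigma_upper = sigma_upper,
                 init_width = init_width), class = "ipm_priors")
}

#' Joint log-density of the integrated population model
#'
#' The (unnormalized) posterior kernel: the multistate CMR log-likelihood,
#' plus the census state-space log-density, plus the log-priors on the
#' hyperparameters and the link-scale year effects.  The decomposition is
#' exactly additive; `-Inf` components propagate to the total.
#'
#' @param rates an `annual_rates` data frame (one row per transition).
#' @param latent data frame with `year`, `N_juv`, `N_ad`, `N_imm`.
#' @param hyper a [hyperparams] object.
#' @param histories a [capture_histories] object or `NULL` (contributes 0).
#' @param census data frame with `year`, `A`, `J`.
#' @param split optional latent survivor split (see
#'   [state_space_logdensity()]).
#' @param priors an [ipm_priors] object.
#' @return a list with `total`, `cmr`, `state_space`, `prior`.
#' @export
joint_log_density <- function(rates, latent, hyper, histories, census,
                              split = NULL, priors = ipm_priors()) {
  rates <- validate_rates(rates)
  cmr <- total_cmr_loglik(histories, rates)
  ss <- state_space_logdensity(latent, census, rates, split = split,
                               init_width = priors$init_width)$total
  prior <- 0
  for (r in .rate_names) {
    mu_r <- hyper$mu[[r]]
    sd_r <- hyper$sigma[[r]]
    prior <- prior + dnorm(mu_r, 0, priors$mu_sd, log = TRUE) +
      dunif(sd_r, 0, priors$sigma_upper, log = TRUE)
    link_vals <- if (r %in% .logit_rates) qlogis(rates[[r]]) else
      log(rates[[r]])
    prior <- prior + sum(dnorm(link_vals, mu_r, sd_r, log = TRUE))
  }
  list(total = cmr + ss + prior, cmr = cmr, state_space = ss, prior = prior)
}

# feasible initial latent path from the raw counts
.init_latent <- function(census, immigration) {
  T_yrs <- nrow(census)
  Nj <- pmax(census$J, 0L)
  Ni <- if (immigration) c(0L, round(0.15 * census$A[-1])) else
    integer(T_yrs)
  Na <- pmax(census$A - Ni, 1L)
  s <- integer(T_yrs - 1L)
  for (t in seq_len(T_yrs - 1L)) {
    # require Na[t+1] - s[t] <= Na[t] + Ni[t] and s[t] <= min(Nj[t], Na[t+1])
    deficit <- Na[t + 1] - (Na[t] + Ni[t]) - Nj[t]
    if (deficit > 0) {
      if (immigration) Ni[t] <- Ni[t] + deficit
      else Na[t] <- Na[t] + deficit
    }
    lo <- max(0L, Na[t + 1] - (Na[t] + Ni[t]))
    hi <- min(Nj[t], Na[t + 1])
    s[t] <- as.integer(max(lo, min(hi, round(0.4 * Nj[t]))))
  }
  list(Nj = as.integer(Nj), Na = as.integer(Na), Ni = as.integer(Ni),
       s = as.integer(s))
}

#' Fit the integrated population model
#'
#' Joint Bayesian inference for the demographic rates, hyperparameters and
#' latent abundances, combining the multistate CMR likelihood and the census
#' state-space density under hierarchical random-year-effect priors.  The
#' sampler is a blocked Metropolis-within-Gibbs: latent capture-state paths
#' are refreshed by forward-filtering backward-sampling, link-scale year
#' effects by adaptive random-walk Metropolis on their local conditionals,
#' hyper-means and year-effect variances by exact Gibbs draws, and latent
#' abundances (with the juvenile-origin survivor split) by integer
#' random-walk Metropolis.  Because the census carries information on all
#' focal-site processes while the CMR data pin down survival and movement,
#' immigration is identified as the shortfall between the two.
#'
#' @param histories a [capture_histories] object (may be `NULL` for a
#'   census-only fit).
#' @param census data frame with `year`, `A`, `J` (female counts; use
#'   [read_census()] with `halve = TRUE` for field counts of both sexes).
#' @param mcmc an [mcmc_config] (default: the `"desk"` preset).
#' @param priors an [ipm_priors] object.
#' @param immigration logical; `FALSE` fixes the immigration rate to zero
#'   (the no-immigration comparison model).
#' @param census_obs census observation law: `"poisson"` (default;
#'   observation variance identified with the mean) or `"normal"` (Gaussian
#'   observation with variances `sigma_J^2`, `sigma_A^2` estimated from the
#'   data).  The Gaussian law lets the model discount the counts when the
#'   demographic process cannot follow them, which is what makes the
#'   no-immigration comparison diverge below an immigration-fed census.
#' @param seed integer seed; fits are exactly reproducible given the seed.
#' @param rhat_threshold convergence warning threshold on the Gelman-Rubin
#'   statistic (default 1.1).
#' @return an object of class `ipm_fit`: list with `draws` (list of `rates`
#'   array draws x rate x year, `latent` array draws x class x year, `hyper`
#'   matrix, `chain`, `iter`), `rhat` (named vector over hyperparameters and
#'   latent abundances), `converged`, `census`, `years`, `mcmc`, `priors`,
#'   `immigration`, `seed`.
#' @examples
#' \donttest{
#' sim <- simulate_ipm_data(n_years = 8, releases_per_year = 15, seed = 1)
#' fit <- fit_ipm(sim$histories, sim$census,
#'                mcmc_config(n_chains = 2, n_iterations = 400,
#'                            n_burnin = 200, thin = 1), seed = 1)
#' coef(fit)
#' }
#' @export
fit_ipm <- function(histories, census, mcmc = mcmc_config("desk"),
                    priors = ipm_priors(), immigration = TRUE,
                    census_obs = c("poisson", "normal"), seed = 1L,
                    rhat_threshold = 1.1) {
  census_obs <- match.arg(census_obs)
  if (!inherits(mcmc, "mcmc_config")) stop("mcmc must be an mcmc_config")
  if (!inherits(priors, "ipm_priors")) stop("priors must be ipm_priors")
  if (!all(c("year", "A", "J") %in% names(census)))
    stop("census must have columns year, A, J")
  if (nrow(census) < 5) stop("need at least 5 years of census data")
  if (any(census$A < 0 | census$J < 0)) stop("census counts must be >= 0")
  if (any(diff(census$year) != 1)) stop("census years must be consecutive")
  T_yrs <- nrow(census)
  if (!is.null(histories)) {
    if (!inherits(histories, "capture_histories"))
      stop("histories must be a capture_histories object")
    if (ncol(histories$obs) != T_yrs)
      stop("capture histories and census must span the same occasions")
  }
  obs <- if (is.null(histories)) matrix(0L, 0, T_yrs) else histories$obs
  release <- if (is.null(histories)) integer(0) else histories$release
  init <- .init_latent(census, immigration)
  nt <- T_yrs - 1L
  base_seed <- (as.integer(seed) %% 1000000L) * 1000L

  chains <- vector("list", mcmc$n_chains)
  for (c_i in seq_len(mcmc$n_chains)) {
    set.seed(base_seed + c_i)
    # overdispersed starting points per chain
    mu_init <- c(rnorm(8, 0, 0.7),
                 log(max(mean(census$J) / max(mean(census$A), 1), 0.02)) +
                   rnorm(1, 0, 0.3),
                 log(0.15) + rnorm(1, 0, 0.5))
    sigma_init <- runif(10, 0.2, 1)
    chains[[c_i]] <- .ipm_mcmc_chain(
      obs, release, as.integer(census$J), as.integer(census$A),
      mcmc$n_iterations, mcmc$n_burnin, mcmc$thin, immigration,
      census_obs == "normal",
      priors$mu_sd, priors$sigma_upper, priors$init_width,
      mu_init, sigma_init, init$Nj, init$Na, init$Ni, init$s)
  }

  n_keep <- (mcmc$n_iterations - mcmc$n_burnin) %/% mcmc$thin
  years_t <- census$year[-T_yrs]
  rates <- array(NA_real_,
                 c(n_keep * mcmc$n_chains, length(.rate_names), nt),
                 dimnames = list(NULL, .rate_names, years_t))
  latent <- array(NA_integer_, c(n_keep * mcmc$n_chains, 3, T_yrs),
                  dimnames = list(NULL, c("N_juv", "N_ad", "N_imm"),
                                  census$year))
  hyper <- matrix(NA_real_, n_keep * mcmc$n_chains, 20,
                  dimnames = list(NULL, c(paste0("mu[", .rate_names, "]"),
                                          paste0("sigma[", .rate_names, "]"))))
  obs_sd <- matrix(NA_real_, n_keep * mcmc$n_chains, 2,
                   dimnames = list(NULL, c("sigma_obs[J]", "sigma_obs[A]")))
  for (c_i in seq_len(mcmc$n_chains)) {
    rows <- (c_i - 1L) * n_keep + seq_len(n_keep)
    rates[rows, , ] <- array(chains[[c_i]]$rates, c(n_keep, nt,
                                                    length(.rate_names)))[,
      , , drop = FALSE] |> aperm(c(1, 3, 2))
    latent[rows, , ] <- array(chains[[c_i]]$latent,
                              c(n_keep, T_yrs, 3)) |> aperm(c(1, 3, 2))
    hyper[rows, ] <- chains[[c_i]]$hyper
    obs_sd[rows, ] <- chains[[c_i]]$obs_sd
  }
  draws <- list(rates = rates, latent = latent, hyper = hyper,
                obs_sd = obs_sd,
                chain = rep(seq_len(mcmc$n_chains), each = n_keep),
                iter = rep(seq_len(n_keep), mcmc$n_chains))

  rhat <- .fit_rhat(draws, immigration)
  converged <- max(rhat, na.rm = TRUE) <= rhat_threshold
  if (!converged)
    warning(sprintf("possible non-convergence: max Gelman-Rubin R-hat %.3f (threshold %.2f)",
                    max(rhat, na.rm = TRUE), rhat_threshold))
  structure(list(draws = draws, rhat = rhat, converged = converged,
                 census = census, years = census$year, mcmc = mcmc,
                 priors = priors, immigration = immigration,
                 census_obs = census_obs, seed = as.integer(seed),
                 n_histories = nrow(obs)),
            class = "ipm_fit")
}

# R-hat over the hyperparameters and the latent abundance series
.fit_rhat <- function(draws, immigration) {
  cols <- colnames(draws$hyper)
  if (!immigration) cols <- setdiff(cols, c("mu[omega]", "sigma[omega]"))
  vals <- vapply(cols, function(p)
    gelman_rubin_matrix(.chain_matrix(draws$hyper[, p], draws$chain)),
    numeric(1))
  lat <- c("N_juv", "N_ad", if (immigration) "N_imm")
  T_yrs <- dim(draws$latent)[3]
  for (cl in lat) {
    v <- vapply(seq_len(T_yrs), function(t)
      gelman_rubin_matrix(.chain_matrix(draws$latent[, cl, t], draws$chain)),
      numeric(1))
    names(v) <- paste0(cl, "[", dimnames(draws$latent)[[3]], "]")
    # skip year-1 N_imm (fixed at zero, zero variance)
    vals <- c(vals, v)
  }
  vals[is.finite(vals)]
}

.chain_matrix <- function(x, chain) {
  ch <- sort(unique(chain))
  sapply(ch, function(c_i) x[chain == c_i])
}

#' Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor: each chain is split in half,
#' and the ratio of pooled-to-within variance is computed over the resulting
#' sequences.  Values near 1 indicate convergence; by default [fit_ipm()]
#' warns above 1.1.
#'
#' @param x an `ipm_fit` object, or a numeric matrix of draws with one column
#'   per chain.
#' @param parameter for a fit: the parameter name, e.g. `"mu[phi_ad_W]"`,
#'   `"phi_ad_W[1985]"`, `"N_ad[1990]"`.
#' @return the point estimate of the potential scale reduction factor.
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  if (inherits(x, "ipm_fit")) {
    if (is.null(parameter)) stop("supply a parameter name")
    v <- .param_draws(x, parameter)
    return(gelman_rubin_matrix(.chain_matrix(v, x$draws$chain)))
  }
  gelman_rubin_matrix(as.matrix(x))
}

#' @rdname gelman_rubin
#' @export
gelman_rubin_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 chains")
  if (nrow(x) < 4) stop("need at least 4 draws per chain")
  half <- nrow(x) %/% 2
  split <- cbind(x[seq_len(half), , drop = FALSE],
                 x[half + seq_len(half), , drop = FALSE])
  m <- ncol(split); n <- nrow(split)
  means <- colMeans(split)
  W <- mean(apply(split, 2, var))
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# extract a scalar draw vector by name
.param_draws <- function(fit, parameter) {
  d <- fit$draws
  if (parameter %in% colnames(d$hyper)) return(d$hyper[, parameter])
  m <- regmatches(parameter, regexec("^([A-Za-z_]+)\\[(\\d+)\\]$", parameter))[[1]]
  if (length(m) == 3) {
    nm <- m[2]; yr <- m[3]
    if (nm %in% .rate_names && yr %in% dimnames(d$rates)[[3]])
      return(d$rates[, nm, yr])
    if (nm %in% dimnames(d$latent)[[2]] && yr %in% dimnames(d$latent)[[3]])
      return(d$latent[, nm, yr])
  }
  stop("unknown parameter '", parameter, "'")
}

#' Posterior summary table
#'
#' Posterior mean, central 95% credible interval and Gelman-Rubin statistic
#' for every scalar in the posterior: hyperparameters (plus the natural-scale
#' hyper-means), annual rates and latent abundances.
#'
#' @param fit an `ipm_fit` object.
#' @param which subset of `c("hyper", "rates", "latent")`.
#' @return a data frame with columns `parameter`, `mean`, `lower`, `upper`,
#'   `rhat`.
#' @export
summarize_posterior <- function(fit, which = c("hyper", "rates", "latent")) {
  d <- fit$draws
  rows <- list()
  summ <- function(nm, v) {
    q <- unname(quantile(v, c(0.025, 0.975)))
    rh <- tryCatch(gelman_rubin_matrix(.chain_matrix(v, d$chain)),
                   error = function(e) NA_real_)
    data.frame(parameter = nm, mean = mean(v), lower = q[1], upper = q[2],
               rhat = rh)
  }
  if ("hyper" %in% which) {
    for (p in colnames(d$hyper)) rows[[p]] <- summ(p, d$hyper[, p])
    if (!is.null(d$obs_sd) && any(d$obs_sd > 0))
      for (p in colnames(d$obs_sd)) rows[[p]] <- summ(p, d$obs_sd[, p])
    for (r in .rate_names) {
      v <- d$hyper[, paste0("mu[", r, "]")]
      v <- if (r %in% .log_rates) exp(v) else plogis(v)
      rows[[paste0("hypermean[", r, "]")]] <- summ(paste0("hypermean[", r, "]"), v)
    }
  }
  if ("rates" %in% which) {
    for (r in .rate_names) for (y in dimnames(d$rates)[[3]]) {
      nm <- paste0(r, "[", y, "]")
      rows[[nm]] <- summ(nm, d$rates[, r, y])
    }
  }
  if ("latent" %in% which) {
    for (cl in dimnames(d$latent)[[2]]) for (y in dimnames(d$latent)[[3]]) {
      nm <- paste0(cl, "[", y, "]")
      rows[[nm]] <- summ(nm, d$latent[, cl, y])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ipm_fit <- function(x, ...) {
  cat("Integrated population model fit\n")
  cat(sprintf("  %d census years (%d-%d), %d capture histories%s\n",
              length(x$years), x$years[1], x$years[length(x$years)],
              x$n_histories,
              if (x$immigration) "" else " [immigration disabled]"))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d draws\n",
              x$mcmc$n_chains, x$mcmc$n_iterations, x$mcmc$n_burnin,
              x$mcmc$thin, length(x$draws$chain)))
  cat(sprintf("  max R-hat %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  cat("  posterior hyper-means (natural scale):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.ipm_fit <- function(object, ...) {
  out <- summarize_posterior(object, ...)
  class(out) <- c("summary.ipm_fit", class(out))
  attr(out, "converged") <- object$converged
  out
}

#' @export
print.summary.ipm_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%d parameters)%s\n", nrow(x),
              if (isTRUE(attr(x, "converged"))) "" else "  [convergence warning]"))
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE,
                   max = 200 * 5)
  invisible(x)
}

#' @export
coef.ipm_fit <- function(object, ...) {
  mu <- colMeans(object$draws$hyper[, paste0("mu[", .rate_names, "]"),
                                    drop = FALSE])
  names(mu) <- .rate_names
  out <- .inv_link_rates(mu)
  if (!object$immigration) out["omega"] <- 0
  out
}

#' @export
plot.ipm_fit <- function(x, ...) {
  d <- x$draws
  yrs <- x$years
  tot <- d$latent[, "N_ad", ] + d$latent[, "N_imm", ]
  juv <- d$latent[, "N_juv", ]
  qs <- function(m) apply(m, 2, quantile, c(0.025, 0.5, 0.975))
  qa <- qs(tot); qj <- qs(juv)
  plot(yrs, x$census$A, pch = 1, ylim = range(0, qa[3, ], x$census$A),
       xlab = "year", ylab = "females",
       main = "Census vs posterior abundance", ...)
  polygon(c(yrs, rev(yrs)), c(qa[1, ], rev(qa[3, ])),
          col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  lines(yrs, qa[2, ], col = "steelblue", lwd = 2)
  points(yrs, x$census$A, pch = 1)
  polygon(c(yrs, rev(yrs)), c(qj[1, ], rev(qj[3, ])),
          col = grDevices::adjustcolor("orange", 0.3), border = NA)
  lines(yrs, qj[2, ], col = "orange", lwd = 2)
  points(yrs, x$census$J, pch = 2)
  legend("topleft", bty = "n",
         legend = c("adults (obs)", "juveniles (obs)",
                    "posterior adults+immigrants", "posterior juveniles"),
         pch = c(1, 2, NA, NA), lwd = c(NA, NA, 2, 2),
         col = c("black", "black", "steelblue", "orange"))
  invisible(x)
}

#' Posterior-predictive census simulation
#'
#' Draws `nsim` replicate census series: for each, a posterior draw of the
#' latent abundances is selected and Poisson observation error applied —
#' useful for graphical posterior-predictive checks against the observed
#' counts.
#'
#' @param object an `ipm_fit` object.
#' @param nsim number of replicate census series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `year`, `A`, `J`.
#' @export
simulate.ipm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$draws
  idx <- sample.int(dim(d$latent)[1], nsim, replace = TRUE)
  lapply(idx, function(i) {
    data.frame(year = object$years,
               A = rpois(length(object$years),
                         d$latent[i, "N_ad", ] + d$latent[i, "N_imm", ]),
               J = rpois(length(object$years), d$latent[i, "N_juv", ]))
  })
}
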