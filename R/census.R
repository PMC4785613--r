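#' Expected next-year abundances under the process equations
#'
#' Deterministic skeleton of the state-space model: the expected numbers of
#' juvenile, adult and immigrant females in year `t + 1` given the year-`t`
#' state and rates,
#' \deqn{E[N_{juv,t+1}] = \beta_t N_{ad,t}}
#' \deqn{E[N_{ad,t+1}] = N_{juv,t}\phi_{juv,W,t}\psi_{juv,WW,t} +
#'   (N_{ad,t}+N_{imm,t})\phi_{ad,W,t}\psi_{ad,WW,t}}
#' \deqn{E[N_{imm,t+1}] = (N_{juv,t}+N_{ad,t}+N_{imm,t})\,\omega_t}
#' with \eqn{\psi_{WW} = 1 - \psi_{WE}} the probability of remaining.
#'
#' @param state_t named vector or one-row data frame with `N_juv`, `N_ad`,
#'   `N_imm`.
#' @param rates_t single row of an `annual_rates` data frame.
#' @return named numeric vector `c(N_juv=, N_ad=, N_imm=)` of expectations.
#' @examples
#' r <- constant_rates(c(phi_juv_W=.7, phi_ad_W=.81, phi_ad_E=.79,
#'                       psi_juv_WE=.16, psi_ad_WE=.09, psi_ad_EW=.2,
#'                       p_W=.86, p_E=.6, beta=.16, omega=.17), 2)
#' step_expectations(c(N_juv = 600, N_ad = 4000, N_imm = 680), r[1, ])
#' @export
step_expectations <- function(state_t, rates_t) {
  s <- as.list(state_t)
  for (nm in c("N_juv", "N_ad", "N_imm")) {
    if (is.null(s[[nm]]) || !is.finite(s[[nm]]) || s[[nm]] < 0)
      stop("state must contain nonnegative ", nm)
  }
  r <- .check_rates_year(rates_t)
  tot <- s$N_juv + s$N_ad + s$N_imm
  c(N_juv = r$beta * s$N_ad,
    N_ad = s$N_juv * r$phi_juv_W * (1 - r$psi_juv_WE) +
      (s$N_ad + s$N_imm) * r$phi_ad_W * (1 - r$psi_ad_WE),
    N_imm = tot * r$omega)
}

#' Log-density of the census state-space model
#'
#' Evaluates the state-space component of the joint model for a given latent
#' abundance path: Poisson process terms for juveniles and immigrants at
#' their expected means, binomial survival terms for adults (juvenile-origin
#' and adult-origin survivor pools), and Poisson observation terms linking
#' latent totals to the observed counts, `J_t ~ Pois(N_juv,t)` and
#' `A_t ~ Pois(N_ad,t + N_imm,t)`.  First-year latent states carry a
#' discrete-uniform prior centred on the first observed counts (half-width
#' `init_width` as a fraction); the first-year immigrant class is fixed at
#' zero (immigrants are arrivals since the start of the series).
#'
#' The adult process is decomposed via the explicit latent `split`: the
#' number of juvenile-origin survivors per transition, so that
#' `split[t] ~ Bin(N_juv,t, phi_juv_W (1 - psi_juv_WE))` and
#' `N_ad,t+1 - split[t] ~ Bin(N_ad,t + N_imm,t, phi_ad_W (1 - psi_ad_WE))`.
#' When `split` is `NULL`, the split is marginalized by summation over its
#' feasible range.
#'
#' @param latent data frame with `year`, `N_juv`, `N_ad`, `N_imm`
#'   (nonnegative integers), one row per census year.
#' @param census data frame with `year`, `A`, `J`, aligned with `latent`.
#' @param rates an `annual_rates` data frame with `nrow(latent) - 1` rows.
#' @param split optional integer vector of juvenile-origin adult survivors
#'   per transition (as returned by [simulate_population()]).
#' @param init_width half-width (fraction of the first counts) of the
#'   first-year discrete-uniform priors.
#' @param obs_law census observation law: `"poisson"` (default; variance
#'   identified with the mean), `"negbin"` (overdispersed) or `"normal"`
#'   (Gaussian with supplied standard deviations `obs_sd` — the free
#'   observation variances `sigma_J^2`, `sigma_A^2`).
#' @param obs_size negative-binomial size when `obs_law = "negbin"`.
#' @param obs_sd named vector `c(J=, A=)` of observation standard deviations
#'   when `obs_law = "normal"`.
#' @return an object of class `ss_density`: list with `process` (data frame of
#'   per-year juvenile/adult/immigrant process log-densities), `observation`
#'   (per-year J and A observation log-densities), and `total`.  Impossible
#'   configurations yield `-Inf` terms, never errors.
#' @export
state_space_logdensity <- function(latent, census, rates, split = NULL,
                                   init_width = 0.5,
                                   obs_law = c("poisson", "negbin", "normal"),
                                   obs_size = 50,
                                   obs_sd = c(J = 30, A = 100)) {
  obs_law <- match.arg(obs_law)
  rates <- validate_rates(rates)
  T_yrs <- nrow(latent)
  if (nrow(census) != T_yrs || nrow(rates) != T_yrs - 1L)
    stop("latent, census and rates are not aligned")
  if (!all(latent$year == census$year))
    stop("latent and census years differ")
  Nj <- latent$N_juv; Na <- latent$N_ad; Ni <- latent$N_imm
  if (any(c(Nj, Na, Ni) < 0) || any(c(Nj, Na, Ni) != round(c(Nj, Na, Ni))))
    stop("latent abundances must be nonnegative integers")

  proc <- data.frame(year = latent$year,
                     juv = 0, ad = 0, imm = 0)
  # First-year discrete-uniform priors (constant within range, -Inf outside)
  proc$juv[1] <- .dunif_int(Nj[1], census$J[1], init_width)
  proc$ad[1] <- .dunif_int(Na[1], census$A[1], init_width)
  proc$imm[1] <- if (Ni[1] == 0L) 0 else -Inf

  for (t in seq_len(T_yrs - 1L)) {
    r <- rates[t, ]
    proc$juv[t + 1] <- dpois(Nj[t + 1], r$beta * Na[t], log = TRUE)
    proc$imm[t + 1] <- dpois(Ni[t + 1], r$omega * (Nj[t] + Na[t] + Ni[t]),
                             log = TRUE)
    qj <- r$phi_juv_W * (1 - r$psi_juv_WE)
    qa <- r$phi_ad_W * (1 - r$psi_ad_WE)
    pool <- Na[t] + Ni[t]
    if (!is.null(split)) {
      s <- split[t]
      proc$ad[t + 1] <- dbinom(s, Nj[t], qj, log = TRUE) +
        dbinom(Na[t + 1] - s, pool, qa, log = TRUE)
    } else {
      lo <- max(0L, Na[t + 1] - pool)
      hi <- min(Nj[t], Na[t + 1])
      if (lo > hi) {
        proc$ad[t + 1] <- -Inf
      } else {
        s <- lo:hi
        lp <- dbinom(s, Nj[t], qj, log = TRUE) +
          dbinom(Na[t + 1] - s, pool, qa, log = TRUE)
        m <- max(lp)
        proc$ad[t + 1] <- if (is.finite(m)) m + log(sum(exp(lp - m))) else -Inf
      }
    }
  }
  dobs <- function(x, mu, sdv) {
    switch(obs_law,
           poisson = dpois(x, mu, log = TRUE),
           negbin = dnbinom(x, size = obs_size, mu = mu, log = TRUE),
           normal = dnorm(x, mu, sdv, log = TRUE))
  }
  observation <- data.frame(year = latent$year,
                            J = dobs(census$J, pmax(Nj, 1e-300), obs_sd[["J"]]),
                            A = dobs(census$A, pmax(Na + Ni, 1e-300),
                                     obs_sd[["A"]]))
  if (obs_law != "normal") {
    # discrete laws with mean 0 put all mass at 0: handle exactly
    zero_j <- Nj == 0
    observation$J[zero_j] <- ifelse(census$J[zero_j] == 0, 0, -Inf)
    zero_a <- (Na + Ni) == 0
    observation$A[zero_a] <- ifelse(census$A[zero_a] == 0, 0, -Inf)
  }

  total <- sum(proc$juv, proc$ad, proc$imm,
               observation$J, observation$A)
  structure(list(process = proc, observation = observation, total = total),
            class = "ss_density")
}

#' @export
print.ss_density <- function(x, ...) {
  cat("State-space log-density breakdown\n")
  cat(sprintf("  process: juv %.3f  ad %.3f  imm %.3f\n",
              sum(x$process$juv), sum(x$process$ad), sum(x$process$imm)))
  cat(sprintf("  observation: J %.3f  A %.3f\n",
              sum(x$observation$J), sum(x$observation$A)))
  cat(sprintf("  total: %.3f\n", x$total))
  invisible(x)
}

# log-density of a discrete uniform on round(c*(1-w)) .. round(c*(1+w)),
# always containing the centre count
.dunif_int <- function(x, centre, width) {
  lo <- round(centre * (1 - width))
  hi <- max(round(centre * (1 + width)), lo)
  if (x < lo || x > hi) -Inf else -log(hi - lo + 1)
}
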