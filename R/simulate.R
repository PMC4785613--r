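#' Simulate the age-structured population and its census
#'
#' Propagates female-only latent abundances at the focal site through the
#' demographic process equations with full demographic stochasticity, and
#' overlays Poisson census observation error.  With `N_juv`, `N_ad`, `N_imm`
#' the latent juvenile, adult and current-year-immigrant females in year `t`:
#' \deqn{N_{juv,t+1} \sim Pois(\beta_t N_{ad,t})}
#' \deqn{N_{ad,t+1} = S_{juv,t} + S_{ad,t}}
#' \deqn{S_{juv,t} \sim Bin(N_{juv,t},\ \phi_{juv,W,t}(1-\psi_{juv,WE,t}))}
#' \deqn{S_{ad,t} \sim Bin(N_{ad,t}+N_{imm,t},\ \phi_{ad,W,t}(1-\psi_{ad,WE,t}))}
#' \deqn{N_{imm,t+1} \sim Pois(\omega_t (N_{juv,t}+N_{ad,t}+N_{imm,t}))}
#' Observed counts are `J_t ~ Pois(N_juv,t)` and `A_t ~ Pois(N_ad,t + N_imm,t)`.
#' The simulator works directly on females; field counts of both sexes should
#' be halved (see [read_census()]) before comparison.
#'
#' @param rates an `annual_rates` data frame (one row per transition).
#' @param initial named vector `c(N_juv=, N_ad=, N_imm=)` of initial latent
#'   counts (year of the first transition).
#' @param seed integer seed.
#' @param obs_law `"poisson"` (default) or `"negbin"` for the census
#'   observation law; `"negbin"` adds overdispersion with size `obs_size`.
#' @param obs_size negative-binomial size parameter when `obs_law = "negbin"`.
#' @return a list with `abundance` (data frame `year`, `N_juv`, `N_ad`,
#'   `N_imm`), `census` (data frame `year`, `A`, `J`) and `split` (the latent
#'   number of juvenile-origin adult survivors per transition, used by the
#'   state-space density).
#' @examples
#' r <- constant_rates(c(phi_juv_W=.7, phi_ad_W=.81, phi_ad_E=.79,
#'                       psi_juv_WE=.16, psi_ad_WE=.09, psi_ad_EW=.2,
#'                       p_W=.86, p_E=.6, beta=.16, omega=.17), 10)
#' sim <- simulate_population(r, seed = 1)
#' sim$census
#' @export
simulate_population <- function(rates,
                                initial = c(N_juv = 600, N_ad = 3400,
                                            N_imm = 0),
                                seed = NULL,
                                obs_law = c("poisson", "negbin"),
                                obs_size = 50) {
  rates <- validate_rates(rates)
  obs_law <- match.arg(obs_law)
  initial <- unlist(initial)[c("N_juv", "N_ad", "N_imm")]
  if (anyNA(initial) || any(initial < 0))
    stop("initial abundances must be named, nonnegative counts")
  if (!is.null(seed)) set.seed(seed)
  n_trans <- nrow(rates)
  T_yrs <- n_trans + 1L
  Nj <- Na <- Ni <- integer(T_yrs)
  Nj[1] <- round(initial[["N_juv"]])
  Na[1] <- round(initial[["N_ad"]])
  Ni[1] <- round(initial[["N_imm"]])
  split <- integer(n_trans)
  for (t in seq_len(n_trans)) {
    rt <- rates[t, ]
    Nj[t + 1] <- rpois(1, rt$beta * Na[t])
    split[t] <- rbinom(1, Nj[t], rt$phi_juv_W * (1 - rt$psi_juv_WE))
    s_ad <- rbinom(1, Na[t] + Ni[t], rt$phi_ad_W * (1 - rt$psi_ad_WE))
    Na[t + 1] <- split[t] + s_ad
    Ni[t + 1] <- rpois(1, rt$omega * (Nj[t] + Na[t] + Ni[t]))
  }
  years <- c(rates$year, rates$year[n_trans] + 1L)
  draw_obs <- function(mu) {
    if (obs_law == "poisson") rpois(length(mu), mu)
    else rnbinom(length(mu), size = obs_size, mu = mu)
  }
  abundance <- data.frame(year = years, N_juv = Nj, N_ad = Na, N_imm = Ni)
  census <- data.frame(year = years,
                       A = draw_obs(Na + Ni),
                       J = draw_obs(Nj))
  list(abundance = abundance, census = census, split = split)
}

#' Capture-history set
#'
#' Container for multistate capture histories of individually marked animals.
#' All animals are marked as juveniles at the focal site W; observation codes
#' are 0 (not seen), 1 (seen at W), 2 (seen elsewhere, E).
#'
#' @param obs integer matrix, one row per individual, one column per annual
#'   occasion, entries in `{0, 1, 2}`.  Column names `y<year>` label occasions.
#' @param years optional integer vector of occasion years (otherwise parsed
#'   from column names, or defaulting to `1:ncol`).
#' @param id optional character vector of individual identifiers.
#' @return an object of class `capture_histories` with elements `obs`,
#'   `release` (first-sighting occasion index per individual), `years`, `id`.
#' @export
capture_histories <- function(obs, years = NULL, id = NULL) {
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  if (is.null(years)) {
    if (!is.null(colnames(obs)) && all(grepl("^y\\d+$", colnames(obs))))
      years <- as.integer(sub("^y", "", colnames(obs)))
    else years <- seq_len(ncol(obs))
  }
  if (length(years) != ncol(obs)) stop("years must match occasion count")
  if (is.null(id)) id <- if (!is.null(rownames(obs))) rownames(obs) else
    sprintf("ind%04d", seq_len(nrow(obs)))
  if (!all(obs %in% 0:2)) stop("observation codes must be in {0, 1, 2}")
  release <- apply(obs != 0, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  if (anyNA(release)) stop("individuals with no sightings at all: ",
                           paste(head(id[is.na(release)]), collapse = ", "))
  bad <- obs[cbind(seq_len(nrow(obs)), release)] != 1L
  if (any(bad))
    stop("first sighting must be code 1 (marked as juvenile at W); offending id: ",
         paste(head(id[bad]), collapse = ", "))
  colnames(obs) <- paste0("y", years)
  structure(list(obs = obs, release = as.integer(release),
                 years = as.integer(years), id = id),
            class = "capture_histories")
}

#' @export
print.capture_histories <- function(x, ...) {
  cat(sprintf("Capture histories: %d individuals, %d occasions (%d-%d)\n",
              nrow(x$obs), ncol(x$obs), x$years[1], x$years[length(x$years)]))
  cat(sprintf("  sightings: %d at W, %d at E\n",
              sum(x$obs == 1) - nrow(x$obs), sum(x$obs == 2)))
  invisible(x)
}

#' @export
length.capture_histories <- function(x) nrow(x$obs)

#' Simulate multistate capture histories
#'
#' Each year a cohort of juveniles is marked at the focal site W.  Latent
#' states evolve through (juvenile at W, adult at W, adult at E, dead) with
#' the transition structure of [transition_matrix()]; observations are emitted
#' with site-specific detection `p_W`/`p_E`, and dead animals are never
#' observed.  Juveniles enter the adult classes at their first transition.
#'
#' @param rates an `annual_rates` data frame with `n` rows; histories span
#'   `n + 1` occasions, with releases at occasions `1..n`.
#' @param releases_per_year number of juveniles marked per occasion (single
#'   value or vector of length `n`).
#' @param seed integer seed.
#' @return a [capture_histories] object.
#' @examples
#' r <- draw_annual_rates(default_hyperparams(), 5, seed = 2)
#' simulate_capture_histories(r, releases_per_year = 10, seed = 3)
#' @export
simulate_capture_histories <- function(rates, releases_per_year, seed = NULL) {
  rates <- validate_rates(rates)
  n_trans <- nrow(rates)
  T_occ <- n_trans + 1L
  releases_per_year <- rep_len(releases_per_year, n_trans)
  if (any(releases_per_year < 0)) stop("releases_per_year must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- sum(releases_per_year)
  obs <- matrix(0L, n, T_occ)
  release <- rep(seq_len(n_trans), releases_per_year)
  for (i in seq_len(n)) {
    f <- release[i]
    obs[i, f] <- 1L
    z <- 1L                        # juvenile at W
    t <- f
    while (t < T_occ && z != 4L) {
      P <- transition_matrix(rates[t, ])
      z <- sample.int(4L, 1L, prob = P[z, ])
      t <- t + 1L
      if (z == 2L && runif(1) < rates$p_W[t - 1]) obs[i, t] <- 1L
      if (z == 3L && runif(1) < rates$p_E[t - 1]) obs[i, t] <- 2L
    }
  }
  years <- c(rates$year, rates$year[n_trans] + 1L)
  capture_histories(obs, years = years)
}

#' Simulate a complete synthetic study
#'
#' Draws annual rates from their hyperparameters, propagates the population,
#' overlays census observation error and generates capture histories — a full
#' synthetic stand-in for a multi-decade marking and census programme, with
#' the generating truth retained for parameter-recovery checks.
#'
#' @param hyper a [hyperparams] object; defaults to [default_hyperparams()],
#'   whose means reproduce the reported posterior-mean rates.
#' @param n_years number of annual transitions (default 27, i.e. 28 occasions).
#' @param releases_per_year juveniles marked per year (default 40, within the
#'   reported 30-60 range).
#' @param initial initial latent abundances (females).
#' @param seed integer seed; all outputs are reproducible given the seed.
#' @param start_year first transition year label.
#' @return an object of class `ipm_simulation`: list with `rates` (truth),
#'   `abundance` (truth), `split`, `census`, `histories`, `hyper`, `seed`.
#' @examples
#' sim <- simulate_ipm_data(n_years = 8, releases_per_year = 15, seed = 1)
#' sim$census
#' @export
simulate_ipm_data <- function(hyper = default_hyperparams(),
                              n_years = 27L,
                              releases_per_year = 40L,
                              initial = c(N_juv = 600, N_ad = 3400,
                                          N_imm = 0),
                              seed = 1L,
                              start_year = 1983L) {
  set.seed(seed)
  rates <- draw_annual_rates(hyper, n_years, seed = NULL,
                             start_year = start_year)
  pop <- simulate_population(rates, initial = initial, seed = NULL)
  histories <- simulate_capture_histories(rates, releases_per_year,
                                          seed = NULL)
  structure(list(rates = rates, abundance = pop$abundance,
                 split = pop$split, census = pop$census,
                 histories = histories, hyper = hyper, seed = seed),
            class = "ipm_simulation")
}

#' @export
print.ipm_simulation <- function(x, ...) {
  cat(sprintf("Synthetic IPM study: %d occasions (%d-%d), %d marked individuals\n",
              nrow(x$census), x$census$year[1],
              x$census$year[nrow(x$census)], length(x$histories)))
  cat(sprintf("  final census: %d adults, %d juveniles (females)\n",
              x$census$A[nrow(x$census)], x$census$J[nrow(x$census)]))
  invisible(x)
}
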