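# Latent states: 1 = alive juvenile at W, 2 = alive adult at W,
#                 3 = alive adult at E, 4 = dead.
# Observation codes: 0 = not seen, 1 = seen at W, 2 = seen at E.

#' Annual transition matrix of the multistate model
#'
#' Row `j`, column `k` is the probability that an individual in latent state
#' `j` in year `t` is in state `k` in year `t + 1`.  Survival acts first
#' (site- and age-specific), then movement among the survivors.  Juveniles
#' that survive become adults; juveniles that emigrate in their first
#' transition enter the adult-E class (juvenile demography is not separately
#' parameterized elsewhere).  Death is absorbing.
#'
#' @param rates_year a single row of an `annual_rates` data frame (or a named
#'   list with the ten rates).
#' @return a 4 x 4 matrix with rows/columns `juv_W`, `ad_W`, `ad_E`, `dead`;
#'   every row sums to 1.
#' @examples
#' r <- constant_rates(c(phi_juv_W=.7, phi_ad_W=.81, phi_ad_E=.79,
#'                       psi_juv_WE=.16, psi_ad_WE=.09, psi_ad_EW=.2,
#'                       p_W=.86, p_E=.6, beta=.16, omega=.17), 2)
#' transition_matrix(r[1, ])
#' @export
transition_matrix <- function(rates_year) {
  r <- .check_rates_year(rates_year)
  states <- c("juv_W", "ad_W", "ad_E", "dead")
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  P[1, ] <- c(0,
              r$phi_juv_W * (1 - r$psi_juv_WE),
              r$phi_juv_W * r$psi_juv_WE,
              1 - r$phi_juv_W)
  P[2, ] <- c(0,
              r$phi_ad_W * (1 - r$psi_ad_WE),
              r$phi_ad_W * r$psi_ad_WE,
              1 - r$phi_ad_W)
  P[3, ] <- c(0,
              r$phi_ad_E * r$psi_ad_EW,
              r$phi_ad_E * (1 - r$psi_ad_EW),
              1 - r$phi_ad_E)
  P[4, 4] <- 1
  P
}

#' Annual emission matrix of the multistate model
#'
#' Row `j`, column `c + 1` is the probability that an individual in latent
#' state `j` at occasion `t + 1` is recorded with observation code `c`
#' (0 not seen, 1 seen at W, 2 seen at E).  Animals at W are resighted with
#' probability `p_W`, animals at E with `p_E`; dead animals are never seen.
#'
#' @inheritParams transition_matrix
#' @return a 4 x 3 matrix; every row sums to 1.
#' @export
emission_matrix <- function(rates_year) {
  r <- .check_rates_year(rates_year)
  states <- c("juv_W", "ad_W", "ad_E", "dead")
  E <- matrix(0, 4, 3, dimnames = list(states, c("code0", "code1", "code2")))
  E[1, ] <- c(1 - r$p_W, r$p_W, 0)
  E[2, ] <- c(1 - r$p_W, r$p_W, 0)
  E[3, ] <- c(1 - r$p_E, 0, r$p_E)
  E[4, ] <- c(1, 0, 0)
  E
}

#' Transition and emission matrices for one year
#'
#' @inheritParams transition_matrix
#' @return a list with elements `transition` ([transition_matrix()]) and
#'   `emission` ([emission_matrix()]).
#' @export
build_transition_and_emission <- function(rates_year) {
  list(transition = transition_matrix(rates_year),
       emission = emission_matrix(rates_year))
}

.check_rates_year <- function(r) {
  r <- as.list(r)
  for (nm in .rate_names) {
    v <- r[[nm]]
    if (is.null(v) || !is.finite(v)) stop("missing or non-finite rate ", nm)
    if (v < 0 || (nm %in% .logit_rates && v > 1))
      stop("rate ", nm, " out of range")
  }
  r
}

# Vectorized forward algorithm over a set of histories.
# obs: integer matrix n x T; release: vector of first occasions; rates: n-1
# transition rows.  Returns per-history log-likelihoods (conditioned on
# release in state juv_W, observation at release not modelled).
.cmr_forward <- function(obs, release, rates) {
  n <- nrow(obs)
  T_occ <- ncol(obs)
  if (nrow(rates) != T_occ - 1L)
    stop("rates must have one row per transition (", T_occ - 1L, ")")
  ll <- numeric(n)
  alpha <- matrix(0, n, 4)
  for (t in seq_len(T_occ - 1L)) {
    alpha[release == t, 1] <- 1
    act <- which(release <= t)
    if (!length(act)) next
    P <- transition_matrix(rates[t, ])
    E <- emission_matrix(rates[t, ])
    a <- alpha[act, , drop = FALSE] %*% P
    em <- t(E[, obs[act, t + 1L] + 1L, drop = FALSE])
    a <- a * em
    sc <- rowSums(a)
    pos <- sc > 0
    ll[act[!pos]] <- -Inf
    a[pos, ] <- a[pos, , drop = FALSE] / sc[pos]
    a[!pos, ] <- 0
    ll[act[pos]] <- ll[act[pos]] + log(sc[pos])
    alpha[act, ] <- a
  }
  ll
}

#' Log-likelihood of one capture history
#'
#' Marginal log-probability of the observation sequence after release, given
#' release as a juvenile at the focal site W, computed by the forward
#' recursion over the latent states (juvenile W, adult W, adult E, dead) —
#' the multistate likelihood contribution of one marked individual.
#'
#' @param history integer vector of observation codes in `{0, 1, 2}`, one per
#'   occasion; all entries before `release` must be 0 and the entry at
#'   `release` must be 1.
#' @param rates an `annual_rates` data frame with `length(history) - 1` rows.
#' @param release occasion index of release; defaults to the first non-zero
#'   entry.
#' @return the log-probability (`-Inf` for an impossible history).
#' @examples
#' r <- constant_rates(c(phi_juv_W=.7, phi_ad_W=.81, phi_ad_E=.79,
#'                       psi_juv_WE=.16, psi_ad_WE=.09, psi_ad_EW=.2,
#'                       p_W=.86, p_E=.6, beta=.16, omega=.17), 1)
#' exp(capture_history_loglik(c(1, 0), r))  # released then never seen
#' @export
capture_history_loglik <- function(history, rates, release = NULL) {
  history <- .check_history(history, release)
  rates <- validate_rates(rates)
  .cmr_forward(matrix(history, 1), attr(history, "release"), rates)
}

#' Brute-force capture-history log-likelihood (enumeration oracle)
#'
#' Sums the probability of the observed sequence over every latent state path
#' consistent with release as a juvenile at W — exact, exponential in the
#' number of occasions, intended as an independent verification oracle for
#' [capture_history_loglik()].
#'
#' @inheritParams capture_history_loglik
#' @param max_occasions refuse enumeration beyond this many post-release
#'   occasions (path count is `4^k`).
#' @return the log-probability.
#' @export
capture_history_loglik_bruteforce <- function(history, rates, release = NULL,
                                              max_occasions = 8L) {
  history <- .check_history(history, release)
  release <- attr(history, "release")
  rates <- validate_rates(rates)
  T_occ <- length(history)
  k <- T_occ - release
  if (k > max_occasions)
    stop("history too long for path enumeration (", k, " > ",
         max_occasions, " post-release occasions)")
  if (k == 0L) return(0)
  Ps <- lapply(release:(T_occ - 1L), function(t) transition_matrix(rates[t, ]))
  Es <- lapply(release:(T_occ - 1L), function(t) emission_matrix(rates[t, ]))
  paths <- as.matrix(expand.grid(rep(list(1:4), k)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    z <- c(1L, paths[i, ])
    pr <- 1
    for (s in seq_len(k)) {
      pr <- pr * Ps[[s]][z[s], z[s + 1L]] *
        Es[[s]][z[s + 1L], history[release + s] + 1L]
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

.check_history <- function(history, release = NULL) {
  history <- as.integer(history)
  if (!all(history %in% 0:2)) stop("observation codes must be in {0, 1, 2}")
  first <- which(history != 0L)[1]
  if (is.null(release)) release <- first
  if (is.na(release)) stop("history contains no sightings (no release)")
  if (history[release] != 1L)
    stop("infeasible history: code at release must be 1 (marked at W)")
  if (release > 1L && any(history[seq_len(release - 1L)] != 0L))
    stop("infeasible history: sightings before release")
  attr(history, "release") <- as.integer(release)
  history
}

#' Total multistate CMR log-likelihood
#'
#' Sum of the marginal log-likelihoods of all capture histories in a set —
#' the CMR component of the joint model.
#'
#' @param histories a [capture_histories] object (an empty set contributes 0).
#' @param rates an `annual_rates` data frame with one row per transition.
#' @return the total log-likelihood (scalar).
#' @export
total_cmr_loglik <- function(histories, rates) {
  if (is.null(histories) || length(histories) == 0L) return(0)
  if (!inherits(histories, "capture_histories"))
    stop("histories must be a capture_histories object")
  rates <- validate_rates(rates)
  sum(.cmr_forward(histories$obs, histories$release, rates))
}
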