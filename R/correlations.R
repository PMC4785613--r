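#' Per capita rate of increase (PCRI) series
#'
#' The annual per capita rate of increase of the focal subpopulation,
#' `N_{t+1} / N_t`, computed on the total latent population (juveniles +
#' adults + current-year immigrants).
#'
#' @param abundance data frame with `year`, `N_juv`, `N_ad`, `N_imm`.
#' @param classes which classes enter the total (default all three; the
#'   censused total).
#' @return data frame `year` (the year of the denominator), `pcri`; entries
#'   with a zero denominator are `NA` with a warning.
#' @examples
#' ab <- data.frame(year = 1:3, N_juv = c(10, 11, 12),
#'                  N_ad = c(90, 99, 108), N_imm = 0)
#' pcri_series(ab)
#' @export
pcri_series <- function(abundance, classes = c("N_juv", "N_ad", "N_imm")) {
  if (nrow(abundance) < 2) stop("need at least two years")
  tot <- Reduce(`+`, lapply(classes, function(cl) abundance[[cl]]))
  pcri <- tot[-1] / tot[-length(tot)]
  if (any(tot[-length(tot)] == 0)) {
    warning("zero population total: PCRI undefined for some years")
    pcri[tot[-length(tot)] == 0] <- NA_real_
  }
  data.frame(year = abundance$year[-nrow(abundance)], pcri = pcri)
}

# Extract a named demographic time series (one value per transition year)
# from the draws of a fit: returns matrix draws x years.
.series_matrix <- function(draws, series) {
  if (is.matrix(series)) return(series)
  rate_alias <- c(immigration = "omega", recruitment = "beta",
                  emigration_juv = "psi_juv_WE", emigration_ad = "psi_ad_WE",
                  survival_juv = "phi_juv_W", survival_ad = "phi_ad_W")
  if (series %in% names(rate_alias)) series <- rate_alias[[series]]
  if (series %in% .rate_names) {
    out <- draws$rates[, series, ]
    return(matrix(out, nrow = dim(draws$rates)[1]))
  }
  if (series == "pcri") {
    T_yrs <- dim(draws$latent)[3]
    tot <- draws$latent[, "N_juv", , drop = FALSE] +
      draws$latent[, "N_ad", , drop = FALSE] +
      draws$latent[, "N_imm", , drop = FALSE]
    tot <- matrix(tot, ncol = T_yrs)
    return(tot[, -1, drop = FALSE] / tot[, -T_yrs, drop = FALSE])
  }
  stop("unknown series '", series, "'; use a rate name, an alias (",
       paste(names(rate_alias), collapse = ", "), "), 'pcri', or a matrix")
}

#' Posterior correlation between two demographic time series
#'
#' Computes the Pearson correlation across years between two demographic
#' series independently within each posterior draw, so that the posterior of
#' the correlation coefficient `r` reflects the joint uncertainty of both
#' series.  Summaries: posterior mean, histogram mode, central 95% credible
#' interval and `P(r > 0)`.
#'
#' @param fit an `ipm_fit` object or a draws list; series may also be given
#'   directly as draws x years matrices.
#' @param series_a,series_b series names — a rate name (`"omega"`, ...), an
#'   alias (`"immigration"`, `"emigration_juv"`, `"emigration_ad"`,
#'   `"survival_juv"`, `"survival_ad"`, `"recruitment"`), `"pcri"` — or
#'   numeric matrices (draws x years).
#' @return an object of class `correlation_result`: list with `pair`, `r`
#'   (per-draw values, `NA`-free), `mean`, `mode`, `cri`, `p_positive`,
#'   `n_excluded` (draws dropped for zero variance).
#' @examples
#' a <- matrix(rnorm(50), 10, 5)
#' posterior_correlation(NULL, a, a)$mean  # series against itself: r = 1
#' @export
posterior_correlation <- function(fit, series_a, series_b) {
  draws <- if (inherits(fit, "ipm_fit")) fit$draws else fit
  A <- .series_matrix(draws, series_a)
  B <- .series_matrix(draws, series_b)
  if (!all(dim(A) == dim(B)))
    stop("series span different draws or years (",
         paste(dim(A), collapse = "x"), " vs ",
         paste(dim(B), collapse = "x"), ")")
  if (ncol(A) < 3) stop("need at least 3 years to correlate")
  sa <- apply(A, 1, sd); sb <- apply(B, 1, sd)
  ok <- sa > 0 & sb > 0
  r <- rep(NA_real_, nrow(A))
  if (any(ok)) {
    Ac <- A[ok, , drop = FALSE] - rowMeans(A[ok, , drop = FALSE])
    Bc <- B[ok, , drop = FALSE] - rowMeans(B[ok, , drop = FALSE])
    r[ok] <- rowSums(Ac * Bc) /
      sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  }
  n_excluded <- sum(!ok)
  r <- r[ok]
  if (!length(r)) stop("all draws had zero variance in a series")
  pair <- paste(
    if (is.matrix(series_a)) "a" else series_a, "~",
    if (is.matrix(series_b)) "b" else series_b)
  structure(list(pair = pair, r = r, mean = mean(r),
                 mode = .hist_mode(r),
                 cri = unname(quantile(r, c(0.025, 0.975))),
                 p_positive = mean(r > 0), n_excluded = n_excluded),
            class = "correlation_result")
}

# kernel-free histogram mode: midpoint of the fullest bin
.hist_mode <- function(x, bins = 50) {
  if (length(unique(x)) == 1) return(x[1])
  h <- hist(x, breaks = bins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' @importFrom graphics hist
NULL

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%s): mean %.3f, mode %.3f, 95%% CRI %.3f-%.3f, P(r>0) = %.3f [%s]\n",
              x$pair, x$mean, x$mode, x$cri[1], x$cri[2], x$p_positive,
              assess_identifiability(x)))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d zero-variance draws excluded)\n", x$n_excluded))
  invisible(x)
}

#' Identifiability of a posterior correlation
#'
#' A correlation is declared identifiable when the posterior probability of a
#' positive coefficient is above `upper` (positive) or below `lower`
#' (negative); otherwise it is not identifiable.
#'
#' @param result a `correlation_result` (or a single probability `P(r > 0)`).
#' @param lower,upper decision thresholds (defaults 0.025 and 0.975).
#' @return `"positive"`, `"negative"` or `"not_identifiable"`.
#' @export
assess_identifiability <- function(result, lower = 0.025, upper = 0.975) {
  p <- if (inherits(result, "correlation_result")) result$p_positive
  else as.numeric(result)
  if (is.na(p) || p < 0 || p > 1) stop("P(r > 0) must be in [0, 1]")
  if (p > upper) "positive" else if (p < lower) "negative"
  else "not_identifiable"
}

#' Standard demographic correlation table
#'
#' Computes the standard pair set: PCRI against immigration, age-specific
#' emigration, age-specific survival and recruitment; immigration against
#' age-specific emigration; and recruitment against age-specific emigration
#' (the compensatory-movement and density-dependence checks).
#'
#' @param fit an `ipm_fit` object.
#' @param pairs optional list of 2-element character vectors overriding the
#'   standard set.
#' @return a data frame with one row per pair: `pair`, `mean`, `mode`,
#'   `cri_lower`, `cri_upper`, `p_positive`, `flag`.
#' @export
demographic_correlations <- function(fit, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- c(lapply(c("immigration", "emigration_juv", "emigration_ad",
                        "survival_juv", "survival_ad", "recruitment"),
                      function(s) c("pcri", s)),
               list(c("immigration", "emigration_juv"),
                    c("immigration", "emigration_ad"),
                    c("recruitment", "emigration_juv"),
                    c("recruitment", "emigration_ad")))
  }
  rows <- lapply(pairs, function(pr) {
    res <- posterior_correlation(fit, pr[1], pr[2])
    data.frame(pair = res$pair, mean = res$mean, mode = res$mode,
               cri_lower = res$cri[1], cri_upper = res$cri[2],
               p_positive = res$p_positive,
               flag = assess_identifiability(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
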