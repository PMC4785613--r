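#' Read and write capture-history CSV files
#'
#' The capture-history dialect is a CSV with header `id,y<first>,...,y<last>`
#' (one column per annual occasion) and cells in `{0, 1, 2}` (not seen / seen
#' at the focal site W / seen elsewhere E).  Reading validates the
#' [capture_histories] invariants: the first sighting of every individual is
#' code 1 (marked as a juvenile at W).  A write followed by a read is
#' bit-identical.
#'
#' @param path file path.
#' @return [read_capture_histories()]: a [capture_histories] object.
#' @export
read_capture_histories <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "id" || !all(grepl("^y\\d+$", names(df)[-1])))
    stop("expected header 'id,y<year>,...' in ", path)
  obs <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(obs) <- "integer")
  if (anyNA(obs) || !all(obs %in% 0:2)) {
    bad <- df$id[rowSums(is.na(obs) |
                           !(obs == 0 | obs == 1 | obs == 2)) > 0]
    stop("cells outside {0,1,2} in ", path, "; offending id: ",
         paste(head(bad), collapse = ", "))
  }
  capture_histories(obs, years = as.integer(sub("^y", "", names(df)[-1])),
                    id = df$id)
}

#' @rdname read_capture_histories
#' @param histories a [capture_histories] object.
#' @export
write_capture_histories <- function(histories, path) {
  if (!inherits(histories, "capture_histories"))
    stop("histories must be a capture_histories object")
  df <- data.frame(id = histories$id, histories$obs, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a census CSV
#'
#' Expects header `year,adults,juveniles` with nonnegative integer counts and
#' strictly consecutive years (no gap imputation).  With `halve = TRUE` the
#' counts are divided by two and rounded half up — the female-only convention
#' for field counts of both sexes under an even sex ratio.
#'
#' @param path file path.
#' @param halve divide counts by 2 (rounding 0.5 up)?
#' @return a data frame with columns `year`, `A` (adult females), `J`
#'   (juvenile females).
#' @export
read_census <- function(path, halve = FALSE) {
  df <- read.csv(path)
  if (!all(c("year", "adults", "juveniles") %in% names(df)))
    stop("expected header 'year,adults,juveniles' in ", path)
  if (anyNA(df) || any(df$adults < 0) || any(df$juveniles < 0) ||
      any(df$adults != round(df$adults)) ||
      any(df$juveniles != round(df$juveniles)))
    stop("census counts must be nonnegative integers")
  if (any(diff(df$year) != 1))
    stop("census years must be consecutive (missing year after ",
         df$year[which(diff(df$year) != 1)[1]], ")")
  half_up <- function(x) floor(x / 2 + 0.5)
  data.frame(year = as.integer(df$year),
             A = as.integer(if (halve) half_up(df$adults) else df$adults),
             J = as.integer(if (halve) half_up(df$juveniles) else
               df$juveniles))
}

#' @rdname read_census
#' @param census data frame with `year`, `A`, `J` (female counts).
#' @export
write_census <- function(census, path) {
  write.csv(data.frame(year = census$year, adults = census$A,
                       juveniles = census$J),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- posterior draws serialization (tidy CSV) -------------------------------

#' Write and read posterior draws as tidy CSV
#'
#' Serializes the draws of an [fit_ipm()] result to a tidy table
#' (`chain, iter, parameter, value`) and reconstructs the draws list from it,
#' so pipeline stages can exchange posteriors losslessly through plain text.
#'
#' @param fit an `ipm_fit` object (or its `draws` element).
#' @param path file path.
#' @return `read_draws()`: a draws list with `rates`, `latent`, `hyper`,
#'   `chain`, `iter`.
#' @export
write_draws <- function(fit, path) {
  d <- if (inherits(fit, "ipm_fit")) fit$draws else fit
  nd <- length(d$chain)
  blocks <- list()
  for (r in dimnames(d$rates)[[2]]) for (y in dimnames(d$rates)[[3]])
    blocks[[paste0(r, "[", y, "]")]] <- d$rates[, r, y]
  for (cl in dimnames(d$latent)[[2]]) for (y in dimnames(d$latent)[[3]])
    blocks[[paste0(cl, "[", y, "]")]] <- d$latent[, cl, y]
  for (h in colnames(d$hyper)) blocks[[h]] <- d$hyper[, h]
  if (!is.null(d$obs_sd))
    for (h in colnames(d$obs_sd)) blocks[[h]] <- d$obs_sd[, h]
  out <- data.frame(chain = rep(d$chain, length(blocks)),
                    iter = rep(d$iter, length(blocks)),
                    parameter = rep(names(blocks), each = nd),
                    value = unlist(blocks, use.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- read.csv(path)
  if (!all(c("chain", "iter", "parameter", "value") %in% names(df)))
    stop("not a tidy draws file: ", path)
  pars <- unique(df$parameter)
  nd <- sum(df$parameter == pars[1])
  parse <- regmatches(pars, regexec("^([A-Za-z_]+)\\[([A-Za-z_0-9]+)\\]$", pars))
  base <- vapply(parse, function(m) if (length(m)) m[2] else "", "")
  idx <- vapply(parse, function(m) if (length(m)) m[3] else "", "")
  years_r <- sort(unique(as.integer(idx[base %in% .rate_names])))
  years_l <- sort(unique(as.integer(idx[base %in% c("N_juv", "N_ad", "N_imm")])))
  val <- function(p) df$value[df$parameter == p]
  rates <- array(NA_real_, c(nd, length(.rate_names), length(years_r)),
                 dimnames = list(NULL, .rate_names, years_r))
  for (r in .rate_names) for (y in years_r)
    rates[, r, as.character(y)] <- val(paste0(r, "[", y, "]"))
  latent <- array(NA_real_, c(nd, 3, length(years_l)),
                  dimnames = list(NULL, c("N_juv", "N_ad", "N_imm"), years_l))
  for (cl in c("N_juv", "N_ad", "N_imm")) for (y in years_l)
    latent[, cl, as.character(y)] <- val(paste0(cl, "[", y, "]"))
  hn <- pars[grepl("^(mu|sigma)\\[", pars)]
  hyper <- sapply(hn, val)
  first <- df[df$parameter == pars[1], ]
  list(rates = rates, latent = latent, hyper = hyper,
       chain = first$chain, iter = first$iter)
}

# ---- run configuration ------------------------------------------------------

#' Run configuration for the command-line pipeline
#'
#' Assembles (optionally from a YAML file) the settings of a pipeline run:
#' input/output paths, MCMC preset, scenario list, correlation pairs, the
#' halving rule for field counts and the seed.  Explicit arguments override
#' file values; the seed is recorded in every artifact the pipeline writes.
#'
#' @param file optional YAML file with any of the fields below.
#' @param ... fields to override: `captures`, `census`, `out_dir`, `preset`,
#'   `scenarios`, `pairs`, `halve`, `seed`, `n_years`, `releases_per_year`,
#'   `immigration`.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(captures = "captures.csv", census = "census.csv",
              out_dir = ".", preset = "desk",
              scenarios = c("full", "no_immigration", "no_migration"),
              pairs = NULL, halve = FALSE, seed = 1L,
              n_years = 27L, releases_per_year = 40L, immigration = TRUE)
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg[names(yaml::read_yaml(file))] <- yaml::read_yaml(file)
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, TRUE)]
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# ---- command-line pipeline --------------------------------------------------

#' Command-line pipeline entry point
#'
#' Subcommands: `simulate` (write synthetic captures, census and the
#' generating truth), `fit` (fit the IPM; write tidy draws, a posterior
#' summary and a run log), `project` (scenario lambda table and source-sink
#' verdict from a draws file), `correlate` (demographic correlation table),
#' and `report` (run the full pipeline and assemble a plain-text report).
#' Designed to back a thin `Rscript` wrapper (see
#' `system.file("cli", "ipmss.R", package = "ipmss")`); all validation errors
#' produce a nonzero status rather than an R error.
#'
#' @param args character vector: subcommand followed by `key=value` options
#'   (`config=<yaml>` loads a [run_config] file first).
#' @return exit status, invisibly: 0 on success, 1 on failure.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' cli_main(c("simulate", paste0("out_dir=", dir), "n_years=6",
#'            "releases_per_year=5", "seed=7"))
#' @export
cli_main <- function(args) {
  status <- tryCatch({
    if (!length(args)) stop("usage: <simulate|fit|project|correlate|report> [key=value ...]")
    cmd <- args[1]
    if (!cmd %in% c("simulate", "fit", "project", "correlate", "report"))
      stop("unknown subcommand '", cmd, "'")
    opts <- .parse_kv(args[-1])
    cfg <- do.call(run_config, c(list(file = opts$config),
                                 opts[setdiff(names(opts), "config")]))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    switch(cmd,
           simulate = .cli_simulate(cfg),
           fit = .cli_fit(cfg),
           project = .cli_project(cfg),
           correlate = .cli_correlate(cfg),
           report = .cli_report(cfg))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_kv <- function(kv) {
  if (!length(kv)) return(list())
  parts <- strsplit(kv, "=", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stop("options must be key=value: ", kv[bad][1])
  vals <- lapply(parts, function(p) {
    v <- paste(p[-1], collapse = "=")
    if (grepl(",", v)) v <- strsplit(v, ",")[[1]]
    if (all(grepl("^-?\\d+$", v))) v <- as.integer(v)
    else if (all(v %in% c("TRUE", "FALSE", "true", "false")))
      v <- as.logical(toupper(v))
    v
  })
  names(vals) <- vapply(parts, `[`, "", 1)
  vals
}

.cli_log <- function(cfg, stage, extra = character()) {
  lines <- c(sprintf("stage: %s", stage),
             sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("seed: %d", cfg$seed),
             sprintf("preset: %s", cfg$preset),
             sprintf("ipmss_version: %s",
                     as.character(utils::packageVersion("ipmss"))),
             extra)
  writeLines(lines, file.path(cfg$out_dir, paste0(stage, "_log.txt")))
}

.cli_simulate <- function(cfg) {
  sim <- simulate_ipm_data(n_years = cfg$n_years,
                           releases_per_year = cfg$releases_per_year,
                           seed = cfg$seed)
  write_capture_histories(sim$histories, file.path(cfg$out_dir, "captures.csv"))
  write_census(sim$census, file.path(cfg$out_dir, "census.csv"))
  truth <- list(seed = cfg$seed,
                hyper_mu = as.list(sim$hyper$mu),
                hyper_sigma = as.list(sim$hyper$sigma),
                rates = lapply(as.list(sim$rates), as.vector),
                abundance = lapply(as.list(sim$abundance), as.vector))
  yaml::write_yaml(truth, file.path(cfg$out_dir, "truth.yaml"))
  .cli_log(cfg, "simulate",
           sprintf("individuals: %d", length(sim$histories)))
  invisible(NULL)
}

.cli_fit <- function(cfg) {
  histories <- read_capture_histories(.in_path(cfg, cfg$captures))
  census <- read_census(.in_path(cfg, cfg$census), halve = cfg$halve)
  if (nrow(census) == 0) stop("empty census")
  fit <- fit_ipm(histories, census, mcmc = mcmc_config(cfg$preset),
                 immigration = cfg$immigration, seed = cfg$seed)
  write_draws(fit, file.path(cfg$out_dir, "draws.csv"))
  write.csv(summarize_posterior(fit),
            file.path(cfg$out_dir, "posterior_summary.csv"),
            row.names = FALSE)
  .cli_log(cfg, "fit",
           c(sprintf("max_rhat: %.4f", max(fit$rhat, na.rm = TRUE)),
             sprintf("converged: %s", fit$converged)))
  invisible(fit)
}

.in_path <- function(cfg, p) {
  if (file.exists(p)) p else file.path(cfg$out_dir, p)
}

.cli_project <- function(cfg, draws = NULL) {
  if (is.null(draws))
    draws <- read_draws(file.path(cfg$out_dir, "draws.csv"))
  tab <- do.call(rbind, lapply(cfg$scenarios, function(sc) {
    sl <- scenario_lambdas(draws, sc)
    data.frame(scenario = sc, lambda_mean = sl$mean,
               cri_lower = sl$cri[1], cri_upper = sl$cri[2])
  }))
  write.csv(tab, file.path(cfg$out_dir, "scenario_lambda.csv"),
            row.names = FALSE)
  verdict <- classify_source_sink(draws)
  writeLines(utils::capture.output(print(verdict)),
             file.path(cfg$out_dir, "verdict.txt"))
  .cli_log(cfg, "project")
  invisible(list(table = tab, verdict = verdict))
}

.cli_correlate <- function(cfg, draws = NULL) {
  if (is.null(draws))
    draws <- read_draws(file.path(cfg$out_dir, "draws.csv"))
  pairs <- if (is.null(cfg$pairs)) NULL else {
    stopifnot(length(cfg$pairs) %% 2 == 0)
    split(cfg$pairs, rep(seq_len(length(cfg$pairs) / 2), each = 2))
  }
  tab <- demographic_correlations(draws, pairs)
  write.csv(tab, file.path(cfg$out_dir, "correlations.csv"),
            row.names = FALSE)
  .cli_log(cfg, "correlate")
  invisible(tab)
}

.cli_report <- function(cfg) {
  .cli_simulate(cfg)
  fit <- .cli_fit(cfg)
  proj <- .cli_project(cfg, fit$draws)
  corr <- .cli_correlate(cfg, fit$draws)
  rep_lines <- c(
    "Integrated population model: source-sink report",
    sprintf("seed %d, preset %s", cfg$seed, cfg$preset), "",
    "Scenario growth rates (dominant eigenvalue):",
    utils::capture.output(print(proj$table, row.names = FALSE)), "",
    utils::capture.output(print(proj$verdict)), "",
    "Demographic correlations:",
    utils::capture.output(print(corr, row.names = FALSE)))
  writeLines(rep_lines, file.path(cfg$out_dir, "report.txt"))
  .cli_log(cfg, "report")
  invisible(NULL)
}
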