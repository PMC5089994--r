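# File formats, configuration, and the command-line entry point.
#
# Response CSV dialect: UTF-8, comma-separated, header
# "respondent_id,item_1,...,item_I", categories coded 1..J.  Categories
# are converted to the internal 0-based scoring on read by the fitter.

#' Write a response matrix to CSV
#'
#' @param sim An `ers_sim`, a responses tibble, or a matrix (categories
#'   1..J).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_responses <- function(sim, path) {
  resp <- if (inherits(sim, "ers_sim")) sim$responses else
    tibble::as_tibble(sim)
  if (!"person" %in% names(resp) && !"respondent_id" %in% names(resp)) {
    resp <- dplyr::bind_cols(tibble::tibble(person = seq_len(nrow(resp))),
                             resp)
  }
  names(resp)[names(resp) == "person"] <- "respondent_id"
  readr::write_csv(resp, path)
  invisible(path)
}

#' Read a response matrix from CSV
#'
#' Expects the dialect written by [write_responses()]; every item column
#' must be an integer category in `1..J`.  A malformed row is reported
#' with its row number.
#'
#' @param path CSV file.
#' @param n_categories Optional J (defaults to the maximum observed).
#' @return A tibble with `person` and `item_*` columns.
#' @export
read_responses <- function(path, n_categories = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "d"))
  names(raw)[names(raw) == "respondent_id"] <- "person"
  item_cols <- grep("^item_", names(raw), value = TRUE)
  if (length(item_cols) == 0L) {
    stop("no `item_*` columns found in ", path, call. = FALSE)
  }
  vals <- as.matrix(raw[item_cols])
  bad <- which(rowSums(is.na(vals) | vals != round(vals) | vals < 1) > 0)
  if (length(bad) > 0L) {
    stop("malformed response row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (values must be integers in 1..J).", call. = FALSE)
  }
  J <- if (is.null(n_categories)) max(vals) else n_categories
  if (max(vals) > J) {
    stop("responses exceed `n_categories` = ", J, call. = FALSE)
  }
  raw
}

#' Write simulation truth to JSON
#'
#' Stores the item bank, person states, design echo and generator model so
#' a recovery analysis can be re-run from files alone.
#'
#' @param sim An `ers_sim`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "ers_sim"))
  jsonlite::write_json(
    list(model = sim$model, n_categories = sim$n_categories,
         items = sim$items, persons = sim$persons),
    path, dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read simulation truth from JSON
#'
#' @param path JSON file written by [write_truth()].
#' @return A list with `model`, `n_categories`, `items`, `persons`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- tibble::as_tibble(x$items)
  class(items) <- c("ers_item_bank", class(items))
  list(model = x$model, n_categories = x$n_categories,
       items = items, persons = tibble::as_tibble(x$persons))
}

#' Read a run configuration from YAML or JSON
#'
#' The configuration mirrors the arguments of [sim_design()],
#' [ers_model_spec()], [prior_spec()] and [mcmc_config()] under the keys
#' `design`, `model`, `priors`, `mcmc`, plus an optional top-level `seed`
#' that overrides the nested seeds.  Unknown keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list of constructed configuration objects.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("design", "model", "priors", "mcmc", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  if (!is.null(cfg$design)) {
    check_args(cfg$design, formals(sim_design), "design")
    out$design <- do.call(sim_design, cfg$design)
  }
  if (!is.null(cfg$model)) {
    check_args(cfg$model, formals(ers_model_spec), "model")
    out$model <- do.call(ers_model_spec, cfg$model)
  }
  if (!is.null(cfg$priors)) {
    check_args(cfg$priors, formals(prior_spec), "priors")
    out$priors <- do.call(prior_spec, cfg$priors)
  }
  if (!is.null(cfg$mcmc)) {
    check_args(cfg$mcmc, formals(mcmc_config), "mcmc")
    out$mcmc <- do.call(mcmc_config, cfg$mcmc)
  }
  if (!is.null(cfg$seed)) {
    if (!is.null(out$design)) out$design$seed <- as.integer(cfg$seed)
    if (!is.null(out$mcmc)) out$mcmc$seed <- as.integer(cfg$seed)
    out$seed <- as.integer(cfg$seed)
  }
  out
}

check_args <- function(given, allowed, where) {
  extra <- setdiff(names(given), names(allowed))
  if (length(extra) > 0L) {
    stop("unknown `", where, "` field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
}

#' Command-line interface
#'
#' Thin dispatcher behind the `inst/cli/ersmix.R` script.  Subcommands:
#' \describe{
#'   \item{simulate}{`--config cfg.yaml --out dir` -- writes
#'     `responses.csv`, `truth.json` and a `design.yaml` echo.}
#'   \item{fit}{`--responses f.csv --model name --out dir [--config cfg]`
#'     -- writes `posterior.json`, `draws.csv`, `psrf.csv`; exits non-zero
#'     when convergence is not declared.}
#'   \item{evaluate}{`--fit dir --truth truth.json --out dir [--misfit
#'     reduced]` -- writes `recovery.json` (and misfit scatter CSV).}
#'   \item{replicate}{`--config cfg.yaml --reps R --out dir` -- repeats
#'     simulate/fit/evaluate and writes the aggregated report.}
#' }
#' All randomness is governed by the seeds in the configuration; outputs
#' record the seed used.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
ersmix_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: ersmix.R <simulate|fit|evaluate|replicate> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  status <- switch(
    cmd,
    simulate = cli_simulate(opts),
    fit = cli_fit(opts),
    evaluate = cli_evaluate(opts),
    replicate = cli_replicate(opts),
    {
      message("unknown subcommand: ", cmd)
      1L
    })
  invisible(as.integer(status))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key,
                                    call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_simulate <- function(opts) {
  cfg <- read_config(opts$config)
  if (is.null(cfg$design)) stop("config must contain a `design` block.",
                                call. = FALSE)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(cfg$design,
                        model = if (!is.null(cfg$model) && cfg$model$cd)
                          "mix-ers-gpcm-cd" else "mix-ers-gpcm")
  write_responses(sim, file.path(opts$out, "responses.csv"))
  write_truth(sim, file.path(opts$out, "truth.json"))
  yaml::write_yaml(unclass(cfg$design), file.path(opts$out, "design.yaml"))
  message("wrote ", nrow(sim$responses), " x ", nrow(sim$items),
          " responses to ", opts$out, " (seed ", cfg$design$seed, ")")
  0L
}

cli_fit <- function(opts) {
  resp <- read_responses(opts$responses)
  model_name <- opts$model %||% "mix-ers-gpcm"
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else list()
  spec <- cfg$model %||% ers_model_spec(model_name,
                                        n_categories =
                                          max(as.matrix(
                                            resp[grep("^item_",
                                                      names(resp))])))
  mcmc <- cfg$mcmc %||% mcmc_config()
  priors <- cfg$priors %||% prior_spec()
  fit <- fit_ersmix(resp, model = spec, priors = priors, mcmc = mcmc)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(model = spec$model, seed = mcmc$seed,
         items = fit$items, classes = fit$classes, person = fit$person,
         bic = model_bic(fit)),
    file.path(opts$out, "posterior.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE)
  readr::write_csv(tibble::as_tibble(do.call(rbind, fit$draws)),
                   file.path(opts$out, "draws.csv"))
  converged <- TRUE
  if (!is.null(fit$psrf)) {
    readr::write_csv(fit$psrf, file.path(opts$out, "psrf.csv"))
    converged <- all(fit$psrf$mpsrf <= 1.10, na.rm = TRUE)
    message("max multivariate PSRF: ",
            round(max(fit$psrf$mpsrf, na.rm = TRUE), 3))
  }
  if (!converged) {
    message("convergence NOT declared (PSRF > 1.10)")
    return(2L)
  }
  0L
}

cli_evaluate <- function(opts) {
  post <- jsonlite::read_json(file.path(opts$fit, "posterior.json"),
                              simplifyVector = TRUE)
  truth <- read_truth(opts$truth)
  person <- tibble::as_tibble(post$person)
  theta_hat <- if ("theta_eap" %in% names(person)) person$theta_eap
               else person$theta_eap_1
  persons <- truth$persons
  omega_true <- ifelse(persons$class == 1L, 1, persons$omega)
  res <- list(
    rmse_theta = rmse(theta_hat, persons$theta),
    bias_theta = bias(theta_hat, persons$theta),
    rmse_omega = rmse(person$omega_eap, omega_true),
    ccr = correct_classification_rate(person$label, persons$label))
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(res, file.path(opts$out, "recovery.json"),
                       dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  0L
}

cli_replicate <- function(opts) {
  cfg <- read_config(opts$config)
  reps <- as.integer(opts$reps %||% 5L)
  res <- replicate_study(cfg$design,
                         model = cfg$model %||% ers_model_spec(),
                         n_replications = reps,
                         mcmc = cfg$mcmc %||% mcmc_config())
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(seed = cfg$design$seed, per_replication = res$per_replication,
         summary = res$summary),
    file.path(opts$out, "replication.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE)
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
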