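# Recovery metrics, misfit analysis, and applied diagnostics.

#' Bias of a set of estimates
#'
#' `mean(estimates) - truth`, over replications (model parameters) or over
#' individuals (person parameters).
#'
#' @param estimates Numeric vector of estimates.
#' @param truth True value (scalar, or vector matched to `estimates`).
#' @return Scalar bias.
#' @export
bias <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("`estimates` is empty.", call. = FALSE)
  mean(estimates - truth)
}

#' Root mean square error of a set of estimates
#'
#' `sqrt(mean((estimates - truth)^2))`; always at least `abs(bias())`.
#'
#' @inheritParams bias
#' @return Non-negative scalar RMSE.
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("`estimates` is empty.", call. = FALSE)
  sqrt(mean((estimates - truth)^2))
}

#' Correct classification rates
#'
#' Per-class rates use the true class sizes as denominators; the pooled
#' rate is the overall share of matches (equivalently the size-weighted
#' mean of the per-class rates).  A macro average over classes is also
#' reported.
#'
#' @param assigned Assigned class labels.
#' @param truth True class labels (same alphabet and length).
#' @return A tibble with one row per class plus `overall` and `macro`.
#' @export
correct_classification_rate <- function(assigned, truth) {
  if (length(assigned) != length(truth)) {
    stop("`assigned` and `truth` must have equal length.", call. = FALSE)
  }
  assigned <- as.character(assigned)
  truth <- as.character(truth)
  extra <- setdiff(unique(assigned), unique(truth))
  if (length(extra) > 0L) {
    stop("assigned labels not present in truth: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  per <- tibble::tibble(class = sort(unique(truth))) |>
    dplyr::mutate(
      n = purrr::map_int(.data$class, ~ sum(truth == .x)),
      ccr = purrr::map_dbl(.data$class,
                           ~ mean(assigned[truth == .x] == .x)))
  dplyr::bind_rows(
    per,
    tibble::tibble(class = "overall", n = length(truth),
                   ccr = mean(assigned == truth)),
    tibble::tibble(class = "macro", n = length(truth),
                   ccr = mean(per$ccr)))
}

#' Person-parameter recovery report for one fitted replication
#'
#' Compares EAP person estimates with the attached simulation truth:
#' RMSE and bias for theta and the effective omega (RMSE over individuals),
#' and classification rates of the modal class assignment.
#'
#' @param fit An `ersmix_fit`.
#' @param sim The generating `ers_sim` (for the truth).
#' @param assigned Optional class assignment overriding the fit's modal
#'   classes (e.g. the naive omega-test classifier).
#' @return A list of class `ers_recovery` with elements `person`
#'   (per-person tibble), `metrics` (one-row tibble) and `ccr` (tibble).
#' @export
recovery_report <- function(fit, sim, assigned = NULL) {
  stopifnot(inherits(sim, "ers_sim"))
  persons <- sim$persons
  th_cols <- grep("^theta", names(persons), value = TRUE)
  theta_true <- persons[[th_cols[1]]]
  theta_hat <- if ("theta_eap" %in% names(fit$person))
    fit$person$theta_eap else fit$person$theta_eap_1
  omega_true <- ifelse(persons$class == 1L, 1, persons$omega)
  omega_hat <- fit$person$omega_eap
  cls_true <- persons$label
  if (is.null(assigned)) {
    assigned <- fit$person$label
  }
  per <- tibble::tibble(
    person = persons$person,
    class_true = cls_true, class_assigned = assigned,
    theta_true = theta_true, theta_hat = theta_hat,
    omega_true = omega_true, omega_hat = omega_hat)
  ccr <- correct_classification_rate(assigned, cls_true)
  metrics <- tibble::tibble(
    rmse_theta = rmse(theta_hat, theta_true),
    bias_theta = bias(theta_hat, theta_true),
    rmse_omega = rmse(omega_hat, omega_true),
    bias_omega = bias(omega_hat, omega_true),
    ccr_overall = ccr$ccr[ccr$class == "overall"])
  structure(list(person = per, metrics = metrics, ccr = ccr),
            class = "ers_recovery")
}

#' @export
print.ers_recovery <- function(x, ...) {
  cat("<ers_recovery>\n")
  print(x$metrics)
  invisible(x)
}

#' Misfit study: consequences of ignoring mixtures (or styles) entirely
#'
#' Fits a reduced model to mixture-generated data: the single-class
#' ERS-GPCM (mixtures ignored; respondents are then screened with the
#' naive omega test, [naive_ers_classify()]) or the plain GPCM (response
#' styles ignored altogether).  Reports classification rates, person
#' RMSE, and the truth-vs-estimate pairs per misclassification type -- the
#' shrinkage of EAP theta estimates toward zero shows up as a regression
#' slope below one for style respondents misclassified as normal.
#'
#' @param sim An `ers_sim` generated from a mixture model (truth required).
#' @param reduced_model `"ers-gpcm"` or `"gpcm"`.
#' @param mcmc An [mcmc_config()].
#' @param priors A [prior_spec()].
#' @return A list of class `ers_misfit`: the reduced-model recovery report
#'   plus `scatter` (misclassified truth-estimate pairs with slopes) and
#'   the reduced `fit`.
#' @export
misfit_study <- function(sim, reduced_model = "ers-gpcm",
                         mcmc = mcmc_config(), priors = prior_spec()) {
  stopifnot(inherits(sim, "ers_sim"))
  reduced_model <- match.arg(reduced_model, c("ers-gpcm", "gpcm"))
  spec <- ers_model_spec(reduced_model, n_categories = sim$n_categories)
  fit <- suppressWarnings(
    fit_ersmix(sim, model = spec, priors = priors, mcmc = mcmc))
  assigned <- if (reduced_model == "ers-gpcm") {
    naive_ers_classify(fit$person$omega_eap, fit$person$omega_sd)
  } else {
    rep("normal", nrow(fit$person))
  }
  rep_ <- recovery_report(fit, sim, assigned = assigned)
  scatter <- rep_$person |>
    dplyr::filter(.data$class_true != .data$class_assigned) |>
    dplyr::mutate(type = paste(.data$class_true, "->",
                               .data$class_assigned))
  slopes <- scatter |>
    dplyr::group_by(.data$type) |>
    dplyr::filter(dplyr::n() >= 3L) |>
    dplyr::summarise(
      n = dplyr::n(),
      slope = stats::coef(stats::lm(theta_hat ~ theta_true))[2],
      .groups = "drop")
  structure(list(person = rep_$person, metrics = rep_$metrics,
                 ccr = rep_$ccr, scatter = scatter, slopes = slopes,
                 fit = fit),
            class = c("ers_misfit", "ers_recovery"))
}

#' Rank-order changes between two sets of latent trait estimates
#'
#' Ranks both vectors (gold standard first) and reports the absolute
#' per-person rank change, plus its maximum and mean.  Rank ties are
#' broken by position (respondent order), so equal inputs give zero
#' change.
#'
#' @param reference Gold-standard estimates.
#' @param alternative Competing estimates (same persons, same order).
#' @return A list of class `rank_change`: `changes` tibble, `max`, `mean`.
#' @export
rank_order_change <- function(reference, alternative) {
  if (length(reference) != length(alternative)) {
    stop("`reference` and `alternative` must have equal length.",
         call. = FALSE)
  }
  r1 <- rank(reference, ties.method = "first")
  r2 <- rank(alternative, ties.method = "first")
  changes <- tibble::tibble(person = seq_along(reference),
                            rank_reference = r1, rank_alternative = r2,
                            change = abs(r1 - r2))
  structure(list(changes = changes, max = max(changes$change),
                 mean = mean(changes$change)),
            class = "rank_change")
}

#' @export
print.rank_change <- function(x, ...) {
  cat("<rank_change> max =", x$max, "| mean =", round(x$mean, 2), "\n")
  invisible(x)
}

#' Item-level propensity to elicit extreme or mild response styles
#'
#' An item's discrimination on the omega dimension measures how strongly
#' response style leaks into its responses; a well-designed item has a
#' low score.  The score is `alpha2`, derived from the MDP split
#' (`sqrt(mdp^2 - alpha1^2)`) when not stored directly.  Class-specific
#' difficulty differences (`|beta_normal - beta_g|`) are reported
#' alongside for latent-DIF screening.
#'
#' @param items An item bank (truth or EAP estimates).
#' @return A tibble with `item`, `score` (= alpha2), `rank` (1 = most
#'   style-prone), and `dif_*` columns per style class.
#' @export
item_ers_elicitation <- function(items) {
  a2 <- items$alpha2
  if (is.null(a2) || all(is.na(a2))) {
    if (is.null(items$mdp) || all(is.na(items$mdp))) {
      stop("item bank provides neither `alpha2` nor `mdp`.", call. = FALSE)
    }
    a2 <- alpha2_from_mdp(items$mdp, items$alpha1)
  }
  out <- tibble::tibble(item = items$item, alpha1 = items$alpha1,
                        score = a2,
                        rank = rank(-a2, ties.method = "first"))
  beta_cols <- grep("^beta_", names(items), value = TRUE)
  if (length(beta_cols) > 1L) {
    for (g in seq_along(beta_cols)[-1]) {
      out[[paste0("dif_", g)]] <-
        abs(items[[beta_cols[1]]] - items[[beta_cols[g]]])
    }
  }
  out
}

#' Repeat simulate / fit / evaluate and aggregate over replications
#'
#' Runs `n_replications` independent replications of a design (seeds
#' derived from the design seed), fits the model, and aggregates person
#' recovery over replications: mean CCR, mean RMSE(theta), mean
#' RMSE(omega), plus per-replication rows.
#'
#' @param design A [sim_design()].
#' @param model An [ers_model_spec()] for the fitted model.
#' @param n_replications Number of replications R.
#' @param mcmc An [mcmc_config()]; the chain seed is offset per
#'   replication.
#' @param generator Generating model passed to [simulate_study()].
#' @return A list of class `ers_replication`: `per_replication` tibble and
#'   `summary` one-row tibble.
#' @export
replicate_study <- function(design, model = ers_model_spec(),
                            n_replications = 5L, mcmc = mcmc_config(),
                            generator = "mix-ers-gpcm") {
  rows <- purrr::map_dfr(seq_len(n_replications), function(r) {
    d <- design
    d$seed <- design$seed + 1000L * (r - 1L)
    sim <- simulate_study(d, model = generator)
    m <- mcmc
    m$seed <- mcmc$seed + 1000L * (r - 1L)
    fit <- suppressWarnings(fit_ersmix(sim, model = model, mcmc = m))
    rec <- recovery_report(fit, sim)
    dplyr::bind_cols(tibble::tibble(replication = r), rec$metrics)
  })
  summary <- rows |>
    dplyr::summarise(n_replications = dplyr::n(),
                     mean_ccr = mean(.data$ccr_overall),
                     mean_rmse_theta = mean(.data$rmse_theta),
                     mean_rmse_omega = mean(.data$rmse_omega))
  structure(list(per_replication = rows, summary = summary),
            class = "ers_replication")
}

#' @export
print.ers_replication <- function(x, ...) {
  cat("<ers_replication>\n")
  print(x$summary)
  invisible(x)
}
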