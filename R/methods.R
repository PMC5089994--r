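# broom-style methods and plotting for fitted objects.

#' Tidy a fitted ERS mixture model
#'
#' @param x An `ersmix_fit`.
#' @param pars Which parameter group to return: `"items"` (structural item
#'   parameters), `"classes"` (mixing proportions and latent-distribution
#'   parameters) or `"persons"` (EAP person estimates).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and (for structural
#'   parameters) `std.error` columns.
#' @export
tidy.ersmix_fit <- function(x, pars = c("items", "classes", "persons"),
                            ...) {
  pars <- match.arg(pars)
  if (pars == "persons") {
    return(x$person |>
             tidyr::pivot_longer(-c("person", "class", "label"),
                                 names_to = "term",
                                 values_to = "estimate"))
  }
  est <- x$estimates
  se <- x$std_errors
  keep <- if (pars == "items") grepl("^alpha1_|^mdp_|^beta_|^tau_",
                                     names(est))
          else grepl("^pi_|^mu_|^sd_", names(est))
  tibble::tibble(term = names(est)[keep],
                 estimate = unname(est[keep]),
                 std.error = unname(se[keep]))
}

#' One-row summary of a fitted ERS mixture model
#'
#' @param x An `ersmix_fit`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, parameter count, max PSRF and
#'   BIC.
#' @export
glance.ersmix_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$model,
    n = nrow(x$person),
    n_items = nrow(x$items),
    n_categories = x$n_categories,
    n_classes = x$model$n_classes,
    k = count_free_parameters(x$model, nrow(x$items), x$n_categories,
                              max(x$subscale)),
    max_mpsrf = if (is.null(x$psrf)) NA_real_ else max(x$psrf$mpsrf,
                                                       na.rm = TRUE),
    bic = model_bic(x))
}

#' Plot a fitted ERS mixture model
#'
#' Shows the posterior person field: EAP omega weight against EAP theta,
#' colored by modal class.  ERS respondents sit below omega = 1, MRS
#' respondents above.
#'
#' @param object An `ersmix_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ersmix_fit <- function(object, ...) {
  th <- if ("theta_eap" %in% names(object$person))
    object$person$theta_eap else object$person$theta_eap_1
  df <- tibble::tibble(theta = th, omega = object$person$omega_eap,
                       class = factor(object$person$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$omega,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = expression(hat(theta) ~ "(EAP)"),
                  y = expression(hat(omega) ~ "(EAP)"),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot category usage by latent class for simulated data
#'
#' Bar chart of category frequencies per generating class; ERS classes
#' pile mass on the endpoint categories, MRS classes on the middle ones.
#'
#' @param object An `ers_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ers_sim <- function(object, ...) {
  df <- object$responses |>
    dplyr::mutate(label = object$persons$label) |>
    tidyr::pivot_longer(dplyr::starts_with("item_"),
                        names_to = "item", values_to = "category")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$category))) +
    ggplot2::geom_bar(ggplot2::aes(y = ggplot2::after_stat(prop),
                                   group = .data$label)) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "response category", y = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot the misclassification shrinkage pattern
#'
#' Truth-versus-estimate scatter for misclassified respondents from a
#' [misfit_study()], with the identity line and per-type regression line;
#' a slope below one reflects the EAP shrinkage of theta toward the prior
#' mean.
#'
#' @param object An `ers_misfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ers_misfit <- function(object, ...) {
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data$theta_true,
                               y = .data$theta_hat)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = expression(theta ~ "(truth)"),
                  y = expression(hat(theta) ~ "(EAP)")) +
    ggplot2::theme_minimal()
}
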