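# Convergence diagnostics, classification, and model comparison.

#' Multivariate potential scale reduction factor
#'
#' Brooks-Gelman multivariate PSRF for a set of parallel chains:
#' `Rp = (n-1)/n + (m+1)/m * lambda1`, where `lambda1` is the largest
#' eigenvalue of `W^{-1} B / n`, `W` the pooled within-chain covariance and
#' `B/n` the between-chain covariance of the chain means.  Values close to
#' one indicate convergence; this package flags blocks above 1.10.
#'
#' @param chains A list of at least two matrices (iterations x parameters)
#'   with equal dimensions, or an `ersmix_fit`.
#' @param ... Unused.
#' @return For matrices: a single numeric value.  For a fit: the per-block
#'   PSRF tibble stored on the object.
#' @export
psrf <- function(chains, ...) {
  if (inherits(chains, "ersmix_fit")) return(chains$psrf)
  m <- length(chains)
  if (m < 2L) stop("PSRF needs at least two chains.", call. = FALSE)
  chains <- lapply(chains, as.matrix)
  dims <- vapply(chains, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all chains must have identical dimensions.", call. = FALSE)
  }
  n <- dims[1, 1]
  p <- dims[2, 1]
  means <- t(vapply(chains, colMeans, numeric(p)))
  W <- Reduce(`+`, lapply(chains, function(x) {
    stats::cov(x)
  })) / m
  Bn <- stats::cov(means)  # = B / n
  # ridge for numerically singular within-chain covariances
  W <- W + diag(1e-10 * max(diag(W), 1e-300), p)
  lambda1 <- max(Re(eigen(solve(W, Bn), only.values = TRUE)$values))
  (n - 1) / n + (m + 1) / m * lambda1
}

#' Univariate potential scale reduction factors
#'
#' Gelman-Rubin `sqrt(Vhat / W)` per parameter, with
#' `Vhat = (n-1)/n W + (1 + 1/m) B/n`.
#'
#' @inheritParams psrf
#' @return Named numeric vector, one entry per parameter.
#' @export
psrf_univariate <- function(chains) {
  m <- length(chains)
  if (m < 2L) stop("PSRF needs at least two chains.", call. = FALSE)
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]])
  W <- Reduce(`+`, lapply(chains, function(x) apply(x, 2L, var))) / m
  means <- t(vapply(chains, colMeans, numeric(ncol(chains[[1]]))))
  Bn <- apply(means, 2L, var)
  vhat <- (n - 1) / n * W + (1 + 1 / m) * Bn
  out <- sqrt(vhat / W)
  out[W == 0 & Bn == 0] <- 1
  out
}

# Per-block PSRF table for a fitted model's structural draws.
psrf_blocks <- function(draws, model) {
  nm <- colnames(draws[[1]])
  blocks <- list(
    alpha = grep("^alpha1_|^mdp_", nm, value = TRUE),
    beta = grep("^beta_", nm, value = TRUE),
    tau = grep("^tau_", nm, value = TRUE),
    class = grep("^pi_|^mu_|^sd_", nm, value = TRUE))
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0L]
  purrr::map_dfr(names(blocks), function(b) {
    cols <- blocks[[b]]
    sub <- lapply(draws, function(d) d[, cols, drop = FALSE])
    keep <- apply(do.call(rbind, sub), 2L, function(x) var(x) > 1e-12)
    mp <- NA_real_
    mr <- NA_real_
    if (any(keep)) {
      sub2 <- lapply(sub, function(d) d[, keep, drop = FALSE])
      if (nrow(sub2[[1]]) > sum(keep) + 2L) {
        mp <- tryCatch(psrf(sub2), error = function(e) NA_real_)
      }
      mr <- max(psrf_univariate(sub2))
      if (is.na(mp)) mp <- mr
    } else {
      mp <- 1; mr <- 1
    }
    tibble::tibble(block = b, n_parameters = length(cols), mpsrf = mp,
                   max_rhat = mr)
  })
}

#' Modal class assignment from posterior membership probabilities
#'
#' Assigns each respondent to the class with the highest posterior
#' membership probability; exact ties are broken toward the normal class.
#'
#' @param x An `ersmix_fit` or a numeric matrix of membership
#'   probabilities (respondents x classes, normal class first).
#' @return Integer vector of class assignments.
#' @export
classify <- function(x) {
  if (inherits(x, "ersmix_fit")) {
    return(x$person$class)
  }
  pm <- as.matrix(x)
  if (any(abs(rowSums(pm) - 1) > 1e-6)) {
    stop("membership probabilities must sum to one per respondent.",
         call. = FALSE)
  }
  apply_modal(pm)
}

#' Naive response-style classification from a single-class fit
#'
#' When the single-class ERS-GPCM is fit (mixtures ignored), respondents
#' can still be screened for response style by testing whether their
#' estimated omega differs from one: the statistic `(omega_hat - 1) / se`
#' sends a respondent to the ERS class below -1.96, to the MRS class above
#' +1.96, and to the normal class otherwise.  The SE is the posterior
#' standard deviation of omega.
#'
#' @param omega_hat Estimated omega weight(s).
#' @param se Positive standard error(s).
#' @return Character vector in `{"normal", "ERS", "MRS"}`.
#' @export
naive_ers_classify <- function(omega_hat, se) {
  if (any(se <= 0)) stop("`se` must be positive.", call. = FALSE)
  stat <- (omega_hat - 1) / se
  dplyr::case_when(stat < -1.96 ~ "ERS", stat > 1.96 ~ "MRS",
                   TRUE ~ "normal")
}

# ---------------------------------------------------------------------------
# observed-data likelihood and BIC

#' Observed-data log-likelihood with random effects integrated out
#'
#' Computes `sum_n log sum_g pi_g integral p(y_n | theta, omega, g)` with
#' the person random effects integrated by Gauss-Hermite quadrature
#' adapted to each class's latent distribution (nodes placed at
#' `mu + sqrt(2) * sigma * x_k`), 15 nodes per dimension by default.  For
#' multidimensional models the subscale likelihoods factor given omega, so
#' the quadrature is one-dimensional per subscale nested in the omega
#' nodes.
#'
#' @param responses Responses accepted by [fit_ersmix()].
#' @param items An item bank (truth or EAP estimates).
#' @param classes A class tibble with columns `mixing`, `theta_mean`,
#'   `theta_var`, `omega_meanlog`, `omega_sdlog` (see `ersmix_fit$classes`).
#' @param model An [ers_model_spec()].
#' @param n_nodes Quadrature nodes per dimension.
#' @return The scalar log-likelihood.
#' @export
marginal_log_likelihood <- function(responses, items, classes, model,
                                    n_nodes = 15L) {
  Y <- response_matrix(responses, model$n_categories)
  J <- attr(Y, "n_categories")
  N <- nrow(Y); I <- ncol(Y)
  G <- nrow(classes)
  gq <- statmod::gauss.quad(n_nodes, kind = "hermite")
  zk <- sqrt(2) * gq$nodes
  wk <- gq$weights / sqrt(pi)
  tau <- tau_matrix(items)
  beta <- beta_matrix(items)
  alpha2 <- item_alpha2(items, model)
  subs <- items$subscale
  S <- max(subs)
  lik <- matrix(0, N, G)
  for (g in seq_len(G)) {
    th_nodes <- classes$theta_mean[g] + sqrt(classes$theta_var[g]) * zk
    if (g == 1L || classes$omega_sdlog[g] == 0) {
      lw_nodes <- if (g == 1L) 0 else classes$omega_meanlog[g]
      lw_w <- 1
    } else {
      lw_nodes <- classes$omega_meanlog[g] + classes$omega_sdlog[g] * zk
      lw_w <- wk
    }
    pg <- numeric(N)
    for (l in seq_along(lw_nodes)) {
      # product over subscales of 1-D theta quadratures, given omega
      tot <- rep(1, N)
      for (s in seq_len(S)) {
        iset <- which(subs == s)
        # log-lik of subscale items at each theta node: N x K
        llk <- matrix(0, N, n_nodes)
        for (i in iset) {
          w_i <- exp(alpha2[i] * lw_nodes[l])
          # category log-probabilities at each node: J x K
          step <- items$alpha1[i] * matrix(th_nodes, J - 1L, n_nodes,
                                           byrow = TRUE) -
            (beta[i, min(g, ncol(beta))] + w_i * tau[i, ])
          cum <- apply(step, 2L, cumsum)
          cum <- rbind(0, cum)
          lp <- sweep(cum, 2L, apply(cum, 2L, function(c) {
            m <- max(c); m + log(sum(exp(c - m)))
          }))
          llk <- llk + lp[Y[, i] + 1L, , drop = FALSE]
        }
        mx <- apply(llk, 1L, max)
        tot <- tot * (exp(mx) * as.numeric(exp(llk - mx) %*% wk))
      }
      pg <- pg + lw_w[min(l, length(lw_w))] * tot
    }
    lik[, g] <- classes$mixing[g] * pg
  }
  sum(log(rowSums(lik)))
}

item_alpha2 <- function(items, model) {
  if (model$cd) {
    a2 <- items$alpha2
    if (any(is.na(a2))) a2 <- alpha2_from_mdp(items$mdp, items$alpha1)
    a2
  } else if (model$model == "gpcm") {
    rep(0, nrow(items))  # weight 1 regardless of omega
  } else {
    rep(1, nrow(items))
  }
}

#' Bayesian information criterion for a fitted model
#'
#' `BIC = -2 logL + k log N`, with the observed-data log-likelihood
#' evaluated at the EAP structural estimates (class membership summed out
#' and person random effects integrated by Gauss-Hermite quadrature; see
#' [marginal_log_likelihood()]), and `k` counting free structural
#' parameters only.  Smaller is better.
#'
#' @param fit An `ersmix_fit`.
#' @param n_nodes Quadrature nodes per dimension.
#' @return The scalar BIC.
#' @export
model_bic <- function(fit, n_nodes = 15L) {
  stopifnot(inherits(fit, "ersmix_fit"))
  ll <- marginal_log_likelihood(fit$data + 1L, fit$items, fit$classes,
                                fit$model, n_nodes = n_nodes)
  if (!is.finite(ll)) stop("non-finite marginal likelihood.", call. = FALSE)
  k <- count_free_parameters(fit$model, nrow(fit$items), fit$n_categories,
                             max(fit$subscale))
  -2 * ll + k * log(nrow(fit$data))
}

count_free_parameters <- function(model, I, J, S = 1L) {
  G <- model$n_classes
  shared_tau <- !is.null(model$restriction) &&
    model$restriction %in% c("GRSM", "RSM")
  fixed_alpha <- !is.null(model$restriction) &&
    model$restriction %in% c("PCM", "RSM")
  k <- 0L
  if (!fixed_alpha) k <- k + I
  if (model$cd) k <- k + S
  k <- k + G * (I - 1L)                      # sum-to-zero difficulties
  k <- k + (if (shared_tau) 1L else I) * (J - 2L)  # sum-to-zero thresholds
  if (G > 1L) {
    k <- k + (G - 1L)                        # mixing
    k <- k + 2L * S * (G - 1L)               # theta means and variances
    k <- k + 2L * (G - 1L)                   # omega log-means and variances
  } else if (model$model == "ers-gpcm") {
    k <- k + 1L                              # omega log-variance
  }
  k
}

#' BIC comparison table over a set of fitted models
#'
#' @param fits A named list of `ersmix_fit` objects.
#' @param n_nodes Quadrature nodes per dimension.
#' @return A tibble with one row per model, sorted by BIC.
#' @export
bic_table <- function(fits, n_nodes = 15L) {
  purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = if (nzchar(nm)) nm else f$model$model,
                   n_classes = f$model$n_classes,
                   k = count_free_parameters(f$model, nrow(f$items),
                                             f$n_categories,
                                             max(f$subscale)),
                   bic = model_bic(f, n_nodes = n_nodes))
  }) |> dplyr::arrange(.data$bic)
}
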