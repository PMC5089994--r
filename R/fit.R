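# Bayesian estimation: adaptive Metropolis-within-Gibbs for the
# ERS-GPCM model family.

#' Prior specification
#'
#' Defaults follow the estimation recipe used throughout the recovery
#' studies: N(0, 4) on location and threshold parameters; lognormal(0, 1)
#' on slopes and the MDP; N(0, 10) on class latent means; Gamma(0.01,
#' 0.01) on class precisions; and N(-0.5, 10) / N(+0.5, 10) on the
#' omega log-means of the ERS and MRS classes (mildly informative centers
#' that, together with the dominant-share constraint on the mixing
#' proportions, guard against label switching).
#'
#' @param location_threshold_var Prior variance for difficulties and
#'   thresholds.
#' @param slope_var Prior variance (log scale) for discriminations and MDP.
#' @param class_mean_var Prior variance for class latent means.
#' @param precision_shape,precision_rate Gamma hyper-parameters for class
#'   precisions.
#' @param omega_logmean_center Prior centers of the omega log-means for
#'   classes 1..G (the normal-class entry is ignored; omega is fixed at 1).
#' @param omega_logmean_var Prior variance of the omega log-means.
#' @param pseudo_logomega_sd Component standard deviation of the fixed
#'   two-component pseudo-prior (centered at the ERS and MRS prior
#'   centers) used to refresh the latent log-omega of normal-class
#'   respondents.  A sampler device only: any proper pseudo-prior leaves
#'   the posterior unchanged, but one that covers the style-class omega
#'   range lets respondents move between classes freely.
#' @return An object of class `ers_prior_spec`.
#' @export
prior_spec <- function(location_threshold_var = 4, slope_var = 1,
                       class_mean_var = 10,
                       precision_shape = 0.01, precision_rate = 0.01,
                       omega_logmean_center = c(0, -0.5, 0.5),
                       omega_logmean_var = 10,
                       pseudo_logomega_sd = 0.6) {
  stopifnot(location_threshold_var > 0, slope_var > 0, class_mean_var > 0,
            omega_logmean_var > 0)
  structure(list(location_threshold_var = location_threshold_var,
                 slope_var = slope_var, class_mean_var = class_mean_var,
                 precision_shape = precision_shape,
                 precision_rate = precision_rate,
                 omega_logmean_center = omega_logmean_center,
                 omega_logmean_var = omega_logmean_var,
                 pseudo_logomega_sd = pseudo_logomega_sd),
            class = "ers_prior_spec")
}

#' MCMC configuration
#'
#' The reference schedule is 15,000 iterations with the first 5,000 as
#' burn-in and three chains; smaller smoke schedules are appropriate for
#' interactive work and continuous testing.
#'
#' @param n_iter Total iterations per chain.
#' @param n_burnin Burn-in iterations (adaptation of proposal scales stops
#'   here).
#' @param n_chains Number of chains (at least 2 for PSRF diagnostics).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return An object of class `ers_mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 15000L, n_burnin = 5000L, n_chains = 3L,
                        thin = 5L, seed = 1L) {
  stopifnot(n_burnin < n_iter, n_chains >= 1L, thin >= 1L)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "ers_mcmc_config")
}

# Coerce responses (ers_sim / tibble / matrix, categories 1..J) to a
# 0-based integer matrix.
response_matrix <- function(responses, n_categories = NULL) {
  if (inherits(responses, "ers_sim")) {
    if (is.null(n_categories)) n_categories <- responses$n_categories
    responses <- responses$responses
  }
  if (is.data.frame(responses)) {
    cols <- grep("^item_", names(responses), value = TRUE)
    if (length(cols) == 0L) {
      cols <- setdiff(names(responses), c("person", "respondent_id"))
    }
    responses <- as.matrix(responses[cols])
  }
  Y <- as.matrix(responses)
  storage.mode(Y) <- "integer"
  if (anyNA(Y)) stop("missing responses are not supported.", call. = FALSE)
  if (min(Y) < 1L) stop("responses must be coded 1..J.", call. = FALSE)
  if (is.null(n_categories)) n_categories <- max(Y)
  if (max(Y) > n_categories) {
    stop("responses exceed `n_categories`.", call. = FALSE)
  }
  structure(Y - 1L, n_categories = as.integer(n_categories))
}

#' Fit an ERS-GPCM family model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler with explicit latent-class
#' indicators.  The identification constraints hold in every retained
#' draw by construction: the normal class has theta ~ N(0,1) and omega
#' fixed at 1; each class's item difficulties average exactly zero; the
#' mixing proportions keep the normal class dominant; and for three-class
#' models the omega log-means are kept ordered (ERS below MRS), so class
#' labels cannot switch across or within chains.
#'
#' @param responses An `ers_sim` object, a tibble with `item_*` columns, or
#'   an N x I matrix of categories `1..J`.
#' @param model An [ers_model_spec()].
#' @param priors An [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param verbose Print per-chain progress.
#' @return An object of class `ersmix_fit`; see [tidy.ersmix_fit()],
#'   [glance.ersmix_fit()], [classify()], [model_bic()], [psrf()].
#' @export
fit_ersmix <- function(responses, model = ers_model_spec(),
                       priors = prior_spec(), mcmc = mcmc_config(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "ers_model_spec"),
            inherits(priors, "ers_prior_spec"),
            inherits(mcmc, "ers_mcmc_config"))
  Y <- response_matrix(responses, model$n_categories)
  J <- attr(Y, "n_categories")
  if (J != model$n_categories) {
    model$n_categories <- J
  }
  N <- nrow(Y); I <- ncol(Y); G <- model$n_classes
  if (G > 1L && (N < 1000L || I < 20L)) {
    warning("mixture models are recommended with at least 1000 respondents ",
            "and 20 items; estimates may be unstable at N = ", N,
            ", I = ", I, ".", call. = FALSE)
  }
  subscale <- rep(1L, I)
  if (model$multidim) {
    if (inherits(responses, "ers_sim") &&
        "subscale" %in% names(responses$items)) {
      subscale <- as.integer(responses$items$subscale)
    } else {
      subscale <- sort(rep(seq_len(model$n_subscales), length.out = I))
    }
    model$n_subscales <- max(subscale)
  }
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    if (verbose) message("chain ", ch, "/", mcmc$n_chains)
    set.seed(mcmc$seed + ch - 1L)
    chains[[ch]] <- run_chain(Y, J, model, priors, mcmc, subscale, verbose)
  }
  assemble_fit(chains, Y, J, model, priors, mcmc, subscale)
}

# ---------------------------------------------------------------------------
# single-chain sampler

run_chain <- function(Y, J, model, priors, mcmc, subscale, verbose = FALSE) {
  N <- nrow(Y); I <- ncol(Y); G <- model$n_classes
  S <- max(subscale)
  cd <- model$cd
  shared_tau <- !is.null(model$restriction) &&
    model$restriction %in% c("GRSM", "RSM")
  fixed_alpha <- !is.null(model$restriction) &&
    model$restriction %in% c("PCM", "RSM")
  free_omega_single <- model$model == "ers-gpcm"

  # --- initial state ------------------------------------------------------
  extreme <- rowMeans(Y == 0L | Y == (J - 1L))
  cls <- rep(1L, N)
  if (G >= 3L) {
    qs <- quantile(extreme, c(0.25, 0.75))
    cls[extreme >= qs[2]] <- 2L
    cls[extreme <= qs[1]] <- 3L
  } else if (G == 2L) {
    cls[extreme >= quantile(extreme, 0.75)] <- 2L
  }
  score <- rowMeans(Y)
  theta <- matrix(0, N, S)
  for (s in seq_len(S)) {
    sc <- rowMeans(Y[, subscale == s, drop = FALSE])
    theta[, s] <- as.numeric(scale(sc)) + rnorm(N, 0, 0.1)
  }
  theta[!is.finite(theta)] <- 0
  omega_center <- rep_len(priors$omega_logmean_center, max(G, 1L))
  mu_omega <- omega_center
  mu_omega[1] <- 0
  sd_omega <- rep(0.4, G)
  if (free_omega_single) mu_omega[1] <- 0
  # data-driven start for the latent threshold weights: respondents with
  # many endpoint responses start with log omega < 0, middle-heavy
  # respondents > 0
  z <- as.numeric(scale(extreme))
  z[!is.finite(z)] <- 0
  logw <- pmin(pmax(-0.7 * z, -1.5), 1.5) + rnorm(N, 0, 0.1)
  if (G > 1L) {
    for (g in 2:G) {
      if (any(cls == g)) mu_omega[g] <- mean(logw[cls == g])
    }
    if (G >= 3L && mu_omega[2] >= mu_omega[3]) {
      mu_omega[2:3] <- sort(mu_omega[2:3])
    }
  }
  mu_theta <- matrix(0, G, S)
  sd_theta <- matrix(1, G, S)
  alpha1 <- rep(1, I)
  mdp_s <- if (cd) rep(1.5, S) else numeric(0)
  alpha2 <- if (cd) alpha2_from_mdp(mdp_s[subscale], alpha1)
            else if (model$model == "gpcm") rep(1, I)
            else rep(1, I)
  if (model$model == "gpcm") {
    logw <- rep(0, N)
  }
  beta <- matrix(0, I, G)
  tau0 <- seq(-0.5, 0.5, length.out = J - 1L)
  tau0 <- tau0 - mean(tau0)
  tau <- matrix(tau0, I, J - 1L, byrow = TRUE)
  pi_g <- if (G > 1L) as.numeric(table(factor(cls, levels = seq_len(G)))) / N
          else 1
  # fixed pseudo-prior for the latent log-omega of normal-class persons:
  # equal mixture of normals at the style-class prior centers
  pseudo_ctr <- if (G >= 2L) omega_center[2:G] else 0
  pseudo_sd <- priors$pseudo_logomega_sd
  pseudo_ldens <- function(x) {
    d <- vapply(pseudo_ctr, function(cc) dnorm(x, cc, pseudo_sd), numeric(length(x)))
    if (is.null(dim(d))) d <- matrix(d, nrow = length(x))
    log(rowMeans(d))
  }
  pseudo_rdraw <- function(n) {
    rnorm(n, sample(pseudo_ctr, n, replace = TRUE), pseudo_sd)
  }

  steps <- list(theta = 0.6, w = 0.4, beta = 0.2, tau = 0.1, alpha = 0.12,
                mdp = 0.08)
  acc <- list(theta = 0, w = 0, beta = 0, tau = 0, alpha = 0, mdp = 0)
  att <- list(theta = 0, w = 0, beta = 0, tau = 0, alpha = 0, mdp = 0)

  omega_free <- G > 1L || free_omega_single  # any person-level omega at all
  logw_eff <- if (G > 1L) ifelse(cls == 1L, 0, logw)
              else if (free_omega_single) logw else rep(0, N)

  ll_fun <- function(th, lw, cl, a1, a2, be, ta) {
    ll_person_cpp(Y, th, subscale, lw, a1, a2, be, cl, ta)
  }

  n_keep <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  par_names <- structural_names(model, I, J, G, S, shared_tau, fixed_alpha,
                                free_omega_single)
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  th_sum <- matrix(0, N, S); th_sq <- matrix(0, N, S)
  w_sum <- numeric(N); w_sq <- numeric(N)
  memb_sum <- matrix(0, N, G)
  n_acc <- 0L
  keep_i <- 0L

  lt_var <- priors$location_threshold_var

  for (it in seq_len(mcmc$n_iter)) {
    ll_cur <- ll_fun(theta, logw_eff, cls, alpha1, alpha2, beta, tau)

    # --- theta ------------------------------------------------------------
    th_prop <- theta + matrix(rnorm(N * S, 0, steps$theta), N, S)
    lp_cur <- rowSums(dnorm(theta, mu_theta[cls, , drop = FALSE],
                            sd_theta[cls, , drop = FALSE], log = TRUE))
    lp_prop <- rowSums(dnorm(th_prop, mu_theta[cls, , drop = FALSE],
                             sd_theta[cls, , drop = FALSE], log = TRUE))
    ll_prop <- ll_fun(th_prop, logw_eff, cls, alpha1, alpha2, beta, tau)
    take <- log(runif(N)) < (ll_prop - ll_cur + lp_prop - lp_cur)
    theta[take, ] <- th_prop[take, ]
    ll_cur[take] <- ll_prop[take]
    acc$theta <- acc$theta + mean(take); att$theta <- att$theta + 1

    # --- person omega (style classes, or all persons for ERS-GPCM) --------
    if (omega_free) {
      elig <- if (G > 1L) cls > 1L else rep(TRUE, N)
      if (any(elig)) {
        lw_prop <- logw
        lw_prop[elig] <- logw[elig] + rnorm(sum(elig), 0, steps$w)
        lwe_prop <- if (G > 1L) ifelse(cls == 1L, 0, lw_prop) else lw_prop
        ll_prop <- ll_fun(theta, lwe_prop, cls, alpha1, alpha2, beta, tau)
        dpri <- dnorm(lw_prop, mu_omega[cls], sd_omega[cls], log = TRUE) -
                dnorm(logw, mu_omega[cls], sd_omega[cls], log = TRUE)
        take <- elig & (log(runif(N)) < (ll_prop - ll_cur + dpri))
        logw[take] <- lw_prop[take]
        ll_cur[take] <- ll_prop[take]
        acc$w <- acc$w + sum(take) / max(sum(elig), 1L)
        att$w <- att$w + 1
      }
      logw_eff <- if (G > 1L) ifelse(cls == 1L, 0, logw) else logw
    }

    # --- class membership (Gibbs with pseudo-prior on latent log-omega) ---
    if (G > 1L) {
      lp <- matrix(0, N, G)
      ll_by_g <- matrix(0, N, G)
      for (g in seq_len(G)) {
        lw_g <- if (g == 1L) rep(0, N) else logw
        ll_g <- ll_fun(theta, lw_g, rep(g, N), alpha1, alpha2, beta, tau)
        ll_by_g[, g] <- ll_g
        th_pri <- rowSums(dnorm(theta,
                                matrix(mu_theta[g, ], N, S, byrow = TRUE),
                                matrix(sd_theta[g, ], N, S, byrow = TRUE),
                                log = TRUE))
        w_pri <- if (g == 1L) pseudo_ldens(logw)
                 else dnorm(logw, mu_omega[g], sd_omega[g], log = TRUE)
        lp[, g] <- log(pi_g[g]) + ll_g + th_pri + w_pri
      }
      lp <- lp - apply(lp, 1L, max)
      pm <- exp(lp)
      pm <- pm / rowSums(pm)
      u <- runif(N)
      cum <- t(apply(pm, 1L, cumsum))
      cls <- 1L + as.integer(rowSums(u > cum))
      cls[cls > G] <- G
      # refresh the latent log-omega of normal-class persons from the
      # pseudo-prior (its full conditional)
      nn <- cls == 1L
      logw[nn] <- pseudo_rdraw(sum(nn))
      logw_eff <- ifelse(cls == 1L, 0, logw)
      ll_cur <- ll_by_g[cbind(seq_len(N), cls)]
      if (it > mcmc$n_burnin) memb_sum <- memb_sum + pm
    }

    # --- item parameters ---------------------------------------------------
    if (I >= 2L) {
      a <- update_beta_cpp(Y, theta, subscale, logw_eff, alpha1, alpha2,
                           beta, cls, tau, steps$beta, lt_var)
      acc$beta <- acc$beta + a / (G * (I - 1L)); att$beta <- att$beta + 1
    }
    if (J >= 3L) {
      a <- update_tau_cpp(Y, theta, subscale, logw_eff, alpha1, alpha2,
                          beta, cls, tau, steps$tau, lt_var, shared_tau)
      np <- if (shared_tau) J - 2L else I * (J - 2L)
      acc$tau <- acc$tau + a / max(np, 1L); att$tau <- att$tau + 1
    }
    if (!fixed_alpha) {
      mdp_item <- if (cd) mdp_s[subscale] else numeric(I)
      a <- update_alpha_cpp(Y, theta, subscale, logw_eff, alpha1, alpha2,
                            beta, cls, tau, steps$alpha, priors$slope_var,
                            cd, mdp_item)
      acc$alpha <- acc$alpha + a / I; att$alpha <- att$alpha + 1
    }
    if (cd) {
      for (s in seq_len(S)) {
        idx <- which(subscale == s)
        lm_cur <- log(mdp_s[s])
        lm_new <- lm_cur + rnorm(1, 0, steps$mdp)
        mdp_new <- exp(lm_new)
        if (mdp_new > max(alpha1[idx])) {
          a2_new <- alpha2
          a2_new[idx] <- sqrt(mdp_new^2 - alpha1[idx]^2)
          ll_old <- ll_subset_cpp(Y, theta, subscale, logw_eff, alpha1,
                                  alpha2, beta, cls, tau, idx, 0L)
          ll_new <- ll_subset_cpp(Y, theta, subscale, logw_eff, alpha1,
                                  a2_new, beta, cls, tau, idx, 0L)
          dpri <- -0.5 * (lm_new^2 - lm_cur^2) / priors$slope_var
          if (log(runif(1)) < ll_new - ll_old + dpri) {
            mdp_s[s] <- mdp_new
            alpha2 <- a2_new
            acc$mdp <- acc$mdp + 1 / S
          }
        }
        att$mdp <- att$mdp + 1 / S
      }
    }

    # --- class-level parameters -------------------------------------------
    if (G > 1L) {
      counts <- tabulate(cls, nbins = G)
      prop <- rgamma(G, shape = 1 + counts, rate = 1)
      prop <- prop / sum(prop)
      if (prop[1] >= max(prop[-1])) pi_g <- prop
      for (g in 2:G) {
        idx <- cls == g
        ng <- sum(idx)
        for (s in seq_len(S)) {
          x <- theta[idx, s]
          prec <- rgamma(1, priors$precision_shape + ng / 2,
                         priors$precision_rate +
                           0.5 * sum((x - mu_theta[g, s])^2))
          sd_theta[g, s] <- clamp_sd(1 / sqrt(prec))
          v1 <- 1 / (ng / sd_theta[g, s]^2 + 1 / priors$class_mean_var)
          m1 <- v1 * sum(x) / sd_theta[g, s]^2
          mu_theta[g, s] <- rnorm(1, m1, sqrt(v1))
        }
        x <- logw[idx]
        prec <- rgamma(1, priors$precision_shape + ng / 2,
                       priors$precision_rate +
                         0.5 * sum((x - mu_omega[g])^2))
        sd_omega[g] <- clamp_sd(1 / sqrt(prec))
        v1 <- 1 / (ng / sd_omega[g]^2 + 1 / priors$omega_logmean_var)
        m1 <- v1 * (sum(x) / sd_omega[g]^2 +
                    omega_center[g] / priors$omega_logmean_var)
        # ordered omega log-means (ERS below MRS) keep labels fixed in
        # every draw
        lo <- -Inf; hi <- Inf
        if (G >= 3L) {
          if (g == 2L) hi <- mu_omega[3] else if (g == 3L) lo <- mu_omega[2]
        }
        mu_omega[g] <- rtrunc_norm(m1, sqrt(v1), lo, hi)
      }
    } else if (free_omega_single) {
      prec <- rgamma(1, priors$precision_shape + N / 2,
                     priors$precision_rate + 0.5 * sum(logw^2))
      sd_omega[1] <- clamp_sd(1 / sqrt(prec))
    }

    # --- adaptation during burn-in ----------------------------------------
    if (it <= mcmc$n_burnin && it %% 50L == 0L) {
      for (nm in names(steps)) {
        if (att[[nm]] > 0) {
          rate <- acc[[nm]] / att[[nm]]
          steps[[nm]] <- steps[[nm]] * exp(0.8 * (rate - 0.35))
          acc[[nm]] <- 0; att[[nm]] <- 0
        }
      }
    }

    # --- storage ------------------------------------------------------------
    if (it > mcmc$n_burnin) {
      th_sum <- th_sum + theta; th_sq <- th_sq + theta^2
      w_eff <- exp(logw_eff)
      w_sum <- w_sum + w_eff; w_sq <- w_sq + w_eff^2
      n_acc <- n_acc + 1L
      if ((it - mcmc$n_burnin) %% mcmc$thin == 0L && keep_i < n_keep) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- structural_vector(
          model, alpha1, mdp_s, beta, tau, pi_g, mu_theta, sd_theta,
          mu_omega, sd_omega, sum(ll_cur), shared_tau, fixed_alpha,
          free_omega_single)
      }
    }
    if (verbose && it %% 1000L == 0L) message("  iter ", it)
  }

  list(draws = draws[seq_len(keep_i), , drop = FALSE],
       th_sum = th_sum, th_sq = th_sq, w_sum = w_sum, w_sq = w_sq,
       memb_sum = memb_sum, n_acc = n_acc, steps = steps)
}

clamp_sd <- function(x) min(max(x, 0.03), 5)

rtrunc_norm <- function(mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) return(min(max(mean, lo + 1e-8), hi - 1e-8))
  qnorm(runif(1, plo, phi), mean, sd)
}

structural_names <- function(model, I, J, G, S, shared_tau, fixed_alpha,
                             free_omega_single) {
  nm <- c()
  if (!fixed_alpha) nm <- c(nm, paste0("alpha1_", seq_len(I)))
  if (model$cd) nm <- c(nm, paste0("mdp_", seq_len(S)))
  nm <- c(nm, paste0("beta_", rep(seq_len(I), G), "_",
                     rep(seq_len(G), each = I)))
  if (shared_tau) nm <- c(nm, paste0("tau_", seq_len(J - 1L)))
  else nm <- c(nm, paste0("tau_", rep(seq_len(I), J - 1L), "_",
                          rep(seq_len(J - 1L), each = I)))
  if (G > 1L) {
    nm <- c(nm, paste0("pi_", seq_len(G)),
            paste0("mu_theta_", rep(2:G, S), "_", rep(seq_len(S), each = G - 1L)),
            paste0("sd_theta_", rep(2:G, S), "_", rep(seq_len(S), each = G - 1L)),
            paste0("mu_omega_", 2:G), paste0("sd_omega_", 2:G))
  } else if (free_omega_single) {
    nm <- c(nm, "sd_omega_1")
  }
  c(nm, "loglik")
}

structural_vector <- function(model, alpha1, mdp_s, beta, tau, pi_g,
                              mu_theta, sd_theta, mu_omega, sd_omega,
                              loglik, shared_tau, fixed_alpha,
                              free_omega_single) {
  G <- ncol(beta)
  v <- c()
  if (!fixed_alpha) v <- c(v, alpha1)
  if (model$cd) v <- c(v, mdp_s)
  v <- c(v, as.numeric(beta))
  v <- c(v, if (shared_tau) tau[1, ] else as.numeric(tau))
  if (G > 1L) {
    v <- c(v, pi_g, as.numeric(mu_theta[-1, , drop = FALSE]),
           as.numeric(sd_theta[-1, , drop = FALSE]),
           mu_omega[-1], sd_omega[-1])
  } else if (free_omega_single) {
    v <- c(v, sd_omega[1])
  }
  c(v, loglik)
}

# ---------------------------------------------------------------------------
# combine chains into the fitted object

assemble_fit <- function(chains, Y, J, model, priors, mcmc, subscale) {
  N <- nrow(Y); I <- ncol(Y); G <- model$n_classes
  S <- max(subscale)
  n_tot <- sum(vapply(chains, function(ch) ch$n_acc, integer(1)))
  th_sum <- Reduce(`+`, lapply(chains, `[[`, "th_sum"))
  th_sq <- Reduce(`+`, lapply(chains, `[[`, "th_sq"))
  w_sum <- Reduce(`+`, lapply(chains, `[[`, "w_sum"))
  w_sq <- Reduce(`+`, lapply(chains, `[[`, "w_sq"))
  memb <- Reduce(`+`, lapply(chains, `[[`, "memb_sum"))

  theta_eap <- th_sum / n_tot
  theta_sd <- sqrt(pmax(th_sq / n_tot - theta_eap^2, 0))
  omega_eap <- w_sum / n_tot
  omega_sd <- sqrt(pmax(w_sq / n_tot - omega_eap^2, 0))

  person <- tibble::tibble(person = seq_len(N))
  if (S == 1L) {
    person$theta_eap <- theta_eap[, 1]
    person$theta_sd <- theta_sd[, 1]
  } else {
    for (s in seq_len(S)) {
      person[[paste0("theta_eap_", s)]] <- theta_eap[, s]
      person[[paste0("theta_sd_", s)]] <- theta_sd[, s]
    }
  }
  person$omega_eap <- omega_eap
  person$omega_sd <- omega_sd
  if (G > 1L) {
    pm <- memb / n_tot
    for (g in seq_len(G)) person[[paste0("p_class_", g)]] <- pm[, g]
    person$class <- apply_modal(pm)
    person$label <- class_labels(G)[person$class]
  } else {
    person$class <- 1L
    person$label <- "normal"
  }

  draws <- lapply(chains, `[[`, "draws")
  est <- colMeans(do.call(rbind, draws))
  se <- apply(do.call(rbind, draws), 2L, sd)

  items <- eap_item_bank(est, model, I, J, G, subscale, draws)
  classes <- eap_classes(est, se, model, G, S)

  psrf_tbl <- NULL
  if (mcmc$n_chains >= 2L) {
    psrf_tbl <- psrf_blocks(draws, model)
    bad <- psrf_tbl$mpsrf > 1.10 | psrf_tbl$max_rhat > 1.10
    if (any(bad, na.rm = TRUE)) {
      warning("convergence not reached (PSRF > 1.10) for block(s): ",
              paste(psrf_tbl$block[which(bad)], collapse = ", "),
              call. = FALSE)
    }
  }

  structure(list(model = model, priors = priors, mcmc = mcmc,
                 person = person, items = items, classes = classes,
                 draws = draws, estimates = est, std_errors = se,
                 psrf = psrf_tbl, subscale = subscale,
                 data = Y, n_categories = J),
            class = "ersmix_fit")
}

apply_modal <- function(pm) {
  # modal class; exact ties resolved toward the normal class (column 1)
  mx <- pm >= apply(pm, 1L, max) - 1e-12
  as.integer(apply(mx, 1L, which.max))
}

eap_item_bank <- function(est, model, I, J, G, subscale, draws) {
  shared_tau <- !is.null(model$restriction) &&
    model$restriction %in% c("GRSM", "RSM")
  fixed_alpha <- !is.null(model$restriction) &&
    model$restriction %in% c("PCM", "RSM")
  alpha1 <- if (fixed_alpha) rep(1, I) else est[paste0("alpha1_", seq_len(I))]
  alpha2 <- rep(NA_real_, I)
  mdp <- rep(NA_real_, I)
  if (model$cd) {
    # EAP of alpha2 computed per draw so the MDP split holds on average
    all_draws <- do.call(rbind, draws)
    a2 <- matrix(0, nrow(all_draws), I)
    for (i in seq_len(I)) {
      a1_d <- all_draws[, paste0("alpha1_", i)]
      m_d <- all_draws[, paste0("mdp_", subscale[i])]
      a2[, i] <- sqrt(pmax(m_d^2 - a1_d^2, 0))
    }
    alpha2 <- colMeans(a2)
    mdp <- est[paste0("mdp_", subscale)]
  } else if (model$model %in% c("mix-ers-gpcm", "ers-gpcm",
                                "mix-ers-gpcm-multidim")) {
    alpha2 <- rep(1, I)
  }
  beta <- matrix(est[paste0("beta_", rep(seq_len(I), G), "_",
                            rep(seq_len(G), each = I))], I, G)
  if (shared_tau) {
    tau <- matrix(est[paste0("tau_", seq_len(J - 1L))], I, J - 1L,
                  byrow = TRUE)
  } else {
    tau <- matrix(est[paste0("tau_", rep(seq_len(I), J - 1L), "_",
                             rep(seq_len(J - 1L), each = I))], I, J - 1L)
  }
  out <- tibble::tibble(item = seq_len(I), subscale = as.integer(subscale),
                        alpha1 = unname(alpha1), alpha2 = unname(alpha2),
                        mdp = unname(mdp))
  for (g in seq_len(G)) out[[paste0("beta_", g)]] <- beta[, g]
  for (j in seq_len(J - 1L)) out[[paste0("tau_", j)]] <- tau[, j]
  class(out) <- c("ers_item_bank", class(out))
  out
}

eap_classes <- function(est, se, model, G, S) {
  labels <- class_labels(G)
  out <- tibble::tibble(class = seq_len(G), label = labels)
  if (G > 1L) {
    out$mixing <- unname(est[paste0("pi_", seq_len(G))])
    mt <- rep(0, G); st <- rep(1, G); mo <- rep(0, G); so <- rep(0, G)
    for (g in 2:G) {
      mt[g] <- est[paste0("mu_theta_", g, "_1")]
      st[g] <- est[paste0("sd_theta_", g, "_1")]
      mo[g] <- est[paste0("mu_omega_", g)]
      so[g] <- est[paste0("sd_omega_", g)]
    }
    out$theta_mean <- mt
    out$theta_var <- st^2
    out$omega_meanlog <- mo
    out$omega_sdlog <- so
  } else {
    out$mixing <- 1
    out$theta_mean <- 0
    out$theta_var <- 1
    out$omega_meanlog <- 0
    out$omega_sdlog <- if ("sd_omega_1" %in% names(est))
      unname(est["sd_omega_1"]) else 0
  }
  out
}

#' @export
print.ersmix_fit <- function(x, ...) {
  cat("<ersmix_fit>", x$model$model, "| N =", nrow(x$person),
      "| I =", nrow(x$items), "| J =", x$n_categories,
      "| G =", x$model$n_classes, "\n")
  cat("chains:", x$mcmc$n_chains, "x", x$mcmc$n_iter, "iterations (",
      x$mcmc$n_burnin, "burn-in )\n")
  if (!is.null(x$psrf)) {
    cat("max multivariate PSRF:", round(max(x$psrf$mpsrf, na.rm = TRUE), 3),
        "\n")
  }
  if (x$model$n_classes > 1L) {
    cat("mixing proportions:",
        paste(round(x$classes$mixing, 3), collapse = " / "), "\n")
  }
  invisible(x)
}
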