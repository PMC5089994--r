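test_that("PSRF matches the brute-force between/within formula", {
  set.seed(7)
  n <- 200
  # 2 chains, 3 parameters
  c1 <- matrix(rnorm(n * 3), n, 3)
  c2 <- matrix(rnorm(n * 3, mean = 0.15), n, 3)
  chains <- list(c1, c2)
  # direct Brooks-Gelman computation
  m <- 2
  W <- (cov(c1) + cov(c2)) / m
  mu <- rbind(colMeans(c1), colMeans(c2))
  Bn <- cov(mu)
  lam <- max(eigen(solve(W, Bn), only.values = TRUE)$values)
  expected <- (n - 1) / n + (m + 1) / m * lam
  expect_equal(psrf(chains), expected, tolerance = 1e-6)
  # univariate version against scalar formula
  Wu <- (apply(c1, 2, var) + apply(c2, 2, var)) / 2
  Bu <- apply(mu, 2, var)
  vh <- (n - 1) / n * Wu + (1 + 1 / m) * Bu
  expect_equal(psrf_univariate(chains), sqrt(vh / Wu), tolerance = 1e-10)
})

test_that("PSRF is near one for identical chains and large for disjoint
          ones", {
  set.seed(8)
  a <- matrix(rnorm(500 * 2), 500, 2)
  expect_equal(psrf(list(a, a)), 1, tolerance = 0.01)
  b <- a + 50
  expect_gt(psrf(list(a, b)), 100)
  expect_error(psrf(list(a)), "two chains")
  expect_error(psrf(list(a, a[1:10, ])), "identical dimensions")
})

test_that("the marginal likelihood matches a brute-force class/quadrature
          oracle", {
  # 3 persons, 2 items, known parameters, 2 classes
  items <- item_bank(alpha1 = c(1.1, 0.8),
                     beta = matrix(c(-0.4, 0.4, 0.3, -0.3), 2, 2),
                     tau = c(-0.5, 0.5), alpha2 = c(1, 1))
  classes <- tibble::tibble(
    class = 1:2, label = c("normal", "ERS"), mixing = c(0.7, 0.3),
    theta_mean = c(0, -0.2), theta_var = c(1, 1.3),
    omega_meanlog = c(0, -0.8), omega_sdlog = c(0, 0.35))
  Y <- rbind(c(1, 3), c(2, 2), c(3, 1))
  spec <- ers_model_spec("mix-ers-gpcm", n_classes = 2, n_categories = 3)
  got <- marginal_log_likelihood(Y, items, classes, spec, n_nodes = 15)
  # oracle: explicit loops over classes and Gauss-Hermite nodes
  gq <- statmod::gauss.quad(15, "hermite")
  lik_oracle <- numeric(3)
  for (n in 1:3) {
    tot <- 0
    for (g in 1:2) {
      pg <- 0
      for (k in 1:15) {
        th <- classes$theta_mean[g] + sqrt(2 * classes$theta_var[g]) *
          gq$nodes[k]
        if (g == 1) {
          p <- 1
          for (i in 1:2) {
            probs <- oracle_probs(th, items$alpha1[i],
                                  beta_matrix(items)[i, g],
                                  tau_matrix(items)[i, ], weight = 1)
            p <- p * probs[Y[n, i]]
          }
          pg <- pg + gq$weights[k] / sqrt(pi) * p
        } else {
          for (l in 1:15) {
            lw <- classes$omega_meanlog[g] +
              sqrt(2) * classes$omega_sdlog[g] * gq$nodes[l]
            p <- 1
            for (i in 1:2) {
              probs <- oracle_probs(th, items$alpha1[i],
                                    beta_matrix(items)[i, g],
                                    tau_matrix(items)[i, ],
                                    weight = exp(lw))
              p <- p * probs[Y[n, i]]
            }
            pg <- pg + gq$weights[k] * gq$weights[l] / pi * p
          }
        }
      }
      tot <- tot + classes$mixing[g] * pg
    }
    lik_oracle[n] <- tot
  }
  expect_equal(got, sum(log(lik_oracle)), tolerance = 1e-6)
})

test_that("free-parameter counts and the BIC penalty are consistent", {
  I <- 20; J <- 4
  k_gpcm <- count_free_parameters(ers_model_spec("gpcm"), I, J)
  k_ers <- count_free_parameters(ers_model_spec("ers-gpcm"), I, J)
  k_mix <- count_free_parameters(ers_model_spec("mix-ers-gpcm"), I, J)
  k_cd <- count_free_parameters(ers_model_spec("mix-ers-gpcm-cd"), I, J)
  # alpha (20) + beta (19) + tau (2 per item)
  expect_equal(k_gpcm, 20 + 19 + 40)
  expect_equal(k_ers, k_gpcm + 1)
  # 3 classes: difficulties per class, mixing, class hypers
  expect_equal(k_mix, 20 + 3 * 19 + 40 + 2 + 4 + 4)
  expect_equal(k_cd, k_mix + 1)
  k_rsm <- count_free_parameters(
    ers_model_spec("mix-ers-gpcm", restriction = "RSM"), I, J)
  expect_equal(k_rsm, 3 * 19 + 2 + 2 + 4 + 4)
  # with equal log-likelihood the richer model pays log(N) per parameter
  expect_gt(-2 * (-100) + k_cd * log(500), -2 * (-100) + k_mix * log(500))
})

test_that("a single-class GPCM fit recovers its generating parameters", {
  d <- sim_design(n_respondents = 400, n_items = 12,
                  class_proportions = 1, omega_meanlog = 0,
                  omega_sdlog = 0, seed = 14)
  sim <- simulate_study(d, model = "gpcm")
  fit <- quiet_fit(sim, model = ers_model_spec("gpcm", n_categories = 4),
                   mcmc = mcmc_config(n_iter = 600, n_burnin = 250,
                                      n_chains = 2, thin = 2, seed = 3))
  expect_gt(cor(fit$items$alpha1, sim$items$alpha1), 0.6)
  expect_gt(cor(fit$items$beta_1, sim$items$beta_1), 0.95)
  expect_gt(cor(fit$person$theta_eap, sim$persons$theta), 0.9)
  # EAP shrinkage: regression of estimate on truth has slope below one
  sl <- coef(lm(fit$person$theta_eap ~ sim$persons$theta))[2]
  expect_lt(sl, 1)
  # thresholds centered per item in every retained draw
  dr <- do.call(rbind, fit$draws)
  tau_d <- dr[, grep("^tau_", colnames(dr))]
  tsum <- matrix(0, nrow(tau_d), 12)
  for (j in 1:3) tsum <- tsum + tau_d[, paste0("tau_", 1:12, "_", j)]
  expect_lt(max(abs(tsum)), 1e-10)
})

test_that("restricted fits honour their constraints in every draw", {
  d <- sim_design(n_respondents = 250, n_items = 8,
                  class_proportions = 1, omega_meanlog = 0,
                  omega_sdlog = 0, seed = 15)
  sim <- simulate_study(d, model = "gpcm")
  fit <- quiet_fit(sim,
                   model = ers_model_spec("gpcm", n_categories = 4,
                                          restriction = "RSM"),
                   mcmc = mcmc_config(n_iter = 300, n_burnin = 120,
                                      n_chains = 1, thin = 2, seed = 4))
  expect_true(all(fit$items$alpha1 == 1))
  # one shared threshold vector
  expect_equal(fit$items$tau_1, rep(fit$items$tau_1[1], 8))
  dr <- fit$draws[[1]]
  expect_true(all(c("tau_1", "tau_2", "tau_3") %in% colnames(dr)))
  expect_false(any(grepl("^alpha1_", colnames(dr))))
})

test_that("fitting degenerate single-class data with the mixture machinery
          matches the single-class fit direction", {
  d <- sim_design(n_respondents = 300, n_items = 10,
                  class_proportions = 1, omega_meanlog = 0,
                  omega_sdlog = 0, seed = 16)
  sim <- simulate_study(d, model = "gpcm")
  f1 <- quiet_fit(sim, model = ers_model_spec("gpcm", n_categories = 4),
                  mcmc = mcmc_config(n_iter = 400, n_burnin = 150,
                                     n_chains = 1, thin = 2, seed = 5))
  # G = 1 ERS-GPCM on the same data: same item structure, omega near 1
  f2 <- quiet_fit(sim, model = ers_model_spec("ers-gpcm",
                                              n_categories = 4),
                  mcmc = mcmc_config(n_iter = 400, n_burnin = 150,
                                     n_chains = 1, thin = 2, seed = 5))
  expect_gt(cor(f1$items$beta_1, f2$items$beta_1), 0.98)
  expect_equal(mean(f2$person$omega_eap), 1, tolerance = 0.2)
})

test_that("warnings flag designs below the recommended size", {
  d <- sim_design(n_respondents = 120, n_items = 6, seed = 19)
  sim <- simulate_study(d)
  expect_warning(
    fit_ersmix(sim, model = ers_model_spec("mix-ers-gpcm",
                                           n_categories = 4),
               mcmc = mcmc_config(n_iter = 60, n_burnin = 20,
                                  n_chains = 1, thin = 1, seed = 1)),
    "at least 1000")
})

test_that("the CD fit keeps the MDP split exact in every draw", {
  d <- sim_design(n_respondents = 400, n_items = 12, mdp = 1.5, seed = 44)
  sim <- simulate_study(d, model = "mix-ers-gpcm-cd")
  fit <- quiet_fit(sim,
                   model = ers_model_spec("mix-ers-gpcm-cd",
                                          n_categories = 4),
                   mcmc = mcmc_config(n_iter = 400, n_burnin = 150,
                                      n_chains = 1, thin = 2, seed = 9))
  dr <- fit$draws[[1]]
  expect_true("mdp_1" %in% colnames(dr))
  # discriminations never exceed the concurrent MDP draw
  a1 <- dr[, paste0("alpha1_", 1:12)]
  expect_true(all(a1 < dr[, "mdp_1"]))
  # EAP alpha2 honours the split on average
  expect_true(all(fit$items$alpha2 >= 0))
  expect_gt(cor(fit$items$alpha1, sim$items$alpha1), 0.5)
})

test_that("multidimensional fits keep subscales separable", {
  d <- sim_design(n_respondents = 400, n_items = 12, n_subscales = 2,
                  theta_cov = matrix(c(1, 0.5, 0.5, 1), 2), mdp = 1.5,
                  seed = 45)
  sim <- simulate_study(d, model = "mix-ers-gpcm-cd")
  fit <- quiet_fit(sim,
                   model = ers_model_spec("mix-ers-gpcm-cd-multidim",
                                          n_subscales = 2,
                                          n_categories = 4),
                   mcmc = mcmc_config(n_iter = 400, n_burnin = 150,
                                      n_chains = 1, thin = 2, seed = 9))
  # each subscale's EAP tracks its own generating trait better than the
  # other subscale's trait
  c11 <- cor(fit$person$theta_eap_1, sim$persons$theta_1)
  c12 <- cor(fit$person$theta_eap_1, sim$persons$theta_2)
  c22 <- cor(fit$person$theta_eap_2, sim$persons$theta_2)
  expect_gt(c11, 0.7)
  expect_gt(c22, 0.7)
  expect_gt(c11, c12)
})
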