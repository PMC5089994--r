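test_that("GPCM probabilities match hand-derived and limiting cases", {
  # flat case: all adjacent log-odds zero
  expect_equal(gpcm_category_probs(0, 1, 0, c(0, 0, 0)), rep(0.25, 4))
  # frozen values from the brute-force oracle at theta = 1
  p <- gpcm_category_probs(1, 1, 0, c(-0.6, 0, 0.6))
  expect_equal(p, c(0.0253, 0.1254, 0.3408, 0.5085), tolerance = 1e-3)
  expect_equal(p, oracle_probs(1, 1, 0, c(-0.6, 0, 0.6)), tolerance = 1e-12)
  # monotone limit: very low trait concentrates mass on the lowest category
  p_lo <- gpcm_category_probs(-50, 1, 0, c(-0.6, 0, 0.6))
  expect_equal(p_lo[1], 1, tolerance = 1e-12)
  # adjacent log-odds identity
  p2 <- gpcm_category_probs(0.3, 1.4, -0.2, c(-0.5, 0.5))
  expect_equal(diff(log(p2)), 1.4 * 0.3 - (-0.2 + c(-0.5, 0.5)),
               tolerance = 1e-12)
  expect_error(gpcm_category_probs(0, -1, 0, c(0, 0)), "positive")
  expect_error(gpcm_category_probs(0, 1, 0, numeric(0)), "at least one")
})

test_that("ERS-GPCM scales thresholds by omega and reduces to the GPCM", {
  tau <- c(-0.6, 0, 0.6)
  expect_identical(ers_gpcm_probs(0.7, 1.2, 0.1, tau, omega = 1),
                   gpcm_category_probs(0.7, 1.2, 0.1, tau))
  expect_equal(ers_gpcm_probs(0.7, 1.2, 0.1, tau, omega = 0.5),
               gpcm_category_probs(0.7, 1.2, 0.1, tau / 2),
               tolerance = 1e-15)
  # an expanded scale (omega > 1) suppresses the extreme categories
  p1 <- ers_gpcm_probs(0, 1, 0, tau, omega = 1)
  p2 <- ers_gpcm_probs(0, 1, 0, tau, omega = 2)
  expect_lt(p2[1] + p2[4], p1[1] + p1[4])
  expect_error(ers_gpcm_probs(0, 1, 0, tau, omega = 0), "positive")
})

test_that("eta weight and the MDP split follow their closed forms", {
  expect_equal(round(eta_weight(c(0.5, 1, 1.5), 0.2), 2),
               c(0.87, 1.00, 1.08))
  expect_equal(eta_weight(1, 5), 1)
  expect_equal(eta_weight(3, 0), 1)
  expect_error(eta_weight(-1, 0.2), "positive")
  expect_equal(alpha2_from_mdp(1.5, 1.5), 0)
  expect_equal(alpha2_from_mdp(1.5, 0.9), 1.2)
  expect_equal(alpha2_from_mdp(1.5, 1.452), 0.37645, tolerance = 1e-4)
  # round-trip conservation
  a2 <- alpha2_from_mdp(1.5, 0.77)
  expect_equal(0.77^2 + a2^2, 1.5^2, tolerance = 1e-12)
  expect_error(alpha2_from_mdp(1.5, 1.6), "exceed")
})

make_bank <- function(G = 3, J = 4, I = 4, mdp = NULL, seed = 1) {
  set.seed(seed)
  beta <- matrix(rnorm(I * G, 0, 0.5), I, G)
  beta <- sweep(beta, 2, colMeans(beta))
  alpha1 <- runif(I, 0.7, 1.4)
  item_bank(alpha1 = alpha1, beta = beta,
            tau = default_grid <- seq(-0.6, 0.6, length.out = J - 1),
            mdp = mdp)
}

test_that("mixture probabilities use class difficulties and force omega = 1
          in the normal class", {
  bank <- make_bank()
  # normal class: identical to the single-class model with omega = 1
  expect_identical(
    mixture_ers_gpcm_probs(0.4, 99, bank, item = 2, class = 1),
    ers_gpcm_probs(0.4, bank$alpha1[2], bank$beta_1[2],
                   c(bank$tau_1[2], bank$tau_2[2], bank$tau_3[2]), 1))
  # a pure difficulty shift moves every adjacent log-odds by the same amount
  shift <- bank$beta_2[3] - bank$beta_1[3]
  p1 <- mixture_ers_gpcm_probs(0.4, 0.8, bank, 3, class = 1)
  bank2 <- bank
  bank2$beta_2[3] <- bank$beta_1[3] + 0.5
  p2 <- mixture_ers_gpcm_probs(0.4, 1, bank2, 3, class = 2)
  expect_equal(diff(log(p2)) - diff(log(p1)), rep(-0.5, 3),
               tolerance = 1e-12)
  expect_error(mixture_ers_gpcm_probs(0, 1, bank, 1, class = 9), "beta_9")
})

test_that("CD model reduces to the mixture model at alpha2 = 1 and to the
          GPCM at alpha2 = 0", {
  bank <- make_bank()
  bank$alpha2 <- rep(1, nrow(bank))
  for (om in c(0.5, 1, 1.9)) {
    expect_equal(cd_model_probs(0.3, om, bank, 2, class = 2),
                 mixture_ers_gpcm_probs(0.3, om, bank, 2, class = 2),
                 tolerance = 1e-15)
  }
  bank$alpha2[2] <- 0
  expect_equal(cd_model_probs(0.3, 0.4, bank, 2, class = 1),
               gpcm_category_probs(0.3, bank$alpha1[2], bank$beta_1[2],
                                   c(bank$tau_1[2], bank$tau_2[2],
                                     bank$tau_3[2])),
               tolerance = 1e-15)
  # worked example: omega 0.5 with alpha2 0.2 scales thresholds by 0.87
  bank$alpha2[3] <- 0.2
  tau3 <- c(bank$tau_1[3], bank$tau_2[3], bank$tau_3[3])
  expect_equal(cd_model_probs(0, 0.5, bank, 3, class = 2),
               ers_gpcm_probs(0, bank$alpha1[3], bank$beta_2[3], tau3,
                              omega = 0.5^0.2),
               tolerance = 1e-15)
  expect_equal(round(0.5^0.2, 2), 0.87)
})

test_that("multidimensional CD model is separable by subscale", {
  bank <- make_bank(mdp = 1.5)
  bank$subscale <- c(1L, 1L, 2L, 2L)
  # S = 1 theta vector reproduces the unidimensional CD model
  expect_identical(multidim_cd_probs(c(0.4), 0.6, make_bank(mdp = 1.5), 2, 2),
                   cd_model_probs(0.4, 0.6, make_bank(mdp = 1.5), 2, 2))
  # items of subscale 1 ignore the second trait component
  p_a <- multidim_cd_probs(c(0.4, -3), 0.6, bank, 1, 2)
  p_b <- multidim_cd_probs(c(0.4, 7), 0.6, bank, 1, 2)
  expect_identical(p_a, p_b)
  # the common omega gives the same eta on items with equal alpha2
  bank$alpha2 <- rep(0.3, 4)
  p1 <- multidim_cd_probs(c(0, 0), 0.5, bank, 1, 2)
  p3 <- multidim_cd_probs(c(0, 0), 0.5, bank, 3, 2)
  expect_equal(p1, oracle_probs(0, bank$alpha1[1], bank$beta_2[1],
                                c(bank$tau_1[1], bank$tau_2[1],
                                  bank$tau_3[1]), weight = 0.5^0.3),
               tolerance = 1e-12)
  expect_equal(p3, oracle_probs(0, bank$alpha1[3], bank$beta_2[3],
                                c(bank$tau_1[3], bank$tau_2[3],
                                  bank$tau_3[3]), weight = 0.5^0.3),
               tolerance = 1e-12)
  bank$subscale[4] <- NA_integer_
  expect_error(multidim_cd_probs(c(0, 0), 1, bank, 4, 1), "subscale")
})

test_that("model restrictions tie parameters and compose idempotently", {
  bank <- make_bank(I = 5)
  pcm <- restrict_model(bank, "PCM")
  expect_true(all(pcm$alpha1 == 1))
  expect_equal(gpcm_category_probs(0.2, 1, pcm$beta_1[1],
                                   c(pcm$tau_1[1], pcm$tau_2[1],
                                     pcm$tau_3[1])),
               mixture_ers_gpcm_probs(0.2, 1, pcm, 1, 1))
  grsm <- restrict_model(bank, "GRSM")
  expect_equal(unlist(grsm[1, c("tau_1", "tau_2", "tau_3")]),
               unlist(grsm[4, c("tau_1", "tau_2", "tau_3")]))
  # beta still shifts the log-odds under a common tau
  pa <- mixture_ers_gpcm_probs(0, 1, grsm, 1, 1)
  pb <- mixture_ers_gpcm_probs(0, 1, grsm, 2, 1)
  expect_equal(diff(log(pa)) - diff(log(pb)),
               rep(grsm$beta_1[2] - grsm$beta_1[1], 3), tolerance = 1e-12)
  # RSM = PCM o GRSM, order-independent
  r1 <- restrict_model(restrict_model(bank, "PCM"), "GRSM")
  r2 <- restrict_model(restrict_model(bank, "GRSM"), "PCM")
  expect_equal(r1, r2)
  expect_equal(restrict_model(bank, "RSM"), r1)
  spec <- restrict_model(ers_model_spec("mix-ers-gpcm"), "PCM")
  expect_identical(spec$restriction, "PCM")
  expect_identical(restrict_model(spec, "GRSM")$restriction, "RSM")
  expect_error(restrict_model(bank, "XYZ"))
})

test_that("probability outputs are normalized and match the oracle on random
          inputs", {
  set.seed(99)
  for (rep in 1:200) {
    J <- sample(2:7, 1)
    tau <- rnorm(J - 1)
    theta <- rnorm(1, 0, 1.5)
    alpha <- runif(1, 0.3, 2)
    beta <- rnorm(1)
    omega <- rlnorm(1, 0, 0.5)
    a2 <- runif(1, 0, 1.4)
    p <- ers_gpcm_probs(theta, alpha, beta, tau, omega)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(p, oracle_probs(theta, alpha, beta, tau, omega),
                 tolerance = 1e-12)
    expect_equal(eta_weight(omega, a2), omega^a2, tolerance = 1e-14)
  }
})

test_that("the compiled likelihood kernel agrees with the R probability
          functions", {
  set.seed(5)
  N <- 25; I <- 6; J <- 5; G <- 3
  bank <- make_bank(G = G, J = J, I = I, seed = 3)
  d <- sim_design(n_respondents = N, n_items = I, n_categories = J,
                  seed = 2)
  sim <- suppressWarnings(simulate_study(d))
  Y <- as.matrix(sim$responses[paste0("item_", 1:I)]) - 1L
  theta <- matrix(rnorm(N), N, 1)
  logw <- rnorm(N, 0, 0.4)
  cls <- sample(1:G, N, replace = TRUE)
  alpha2 <- runif(I, 0, 1.2)
  items <- sim$items
  tau <- as.matrix(items[paste0("tau_", 1:(J - 1))])
  beta <- as.matrix(items[paste0("beta_", 1:G)])
  ll_cpp <- ersmix:::ll_person_cpp(Y, theta, rep(1L, I), logw,
                                   items$alpha1, alpha2, beta, cls, tau)
  ll_r <- vapply(seq_len(N), function(n) {
    sum(vapply(seq_len(I), function(i) {
      w <- exp(alpha2[i] * logw[n])
      p <- ers_gpcm_probs(theta[n, 1], items$alpha1[i], beta[i, cls[n]],
                          tau[i, ], w)
      log(p[Y[n, i] + 1L])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
})
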