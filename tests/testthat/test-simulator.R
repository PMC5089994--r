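test_that("simulation designs validate their inputs", {
  expect_error(sim_design(class_proportions = c(0.3, 0.4, 0.3)), "dominant")
  expect_error(sim_design(class_proportions = c(0.6, 0.3)), "sum to one")
  expect_error(sim_design(tau_grid = c(-1, 0)), "length")
  expect_error(sim_design(tau_grid = c(0, 0.5, 1)), "mean zero")
  d <- sim_design(n_categories = 6)
  expect_equal(d$tau_grid, c(-0.8, -0.4, 0, 0.4, 0.8))
})

test_that("item banks have centered class difficulties and balanced shifts", {
  d <- sim_design(n_items = 20, seed = 3)
  set.seed(d$seed)
  bank <- sim_item_bank(d)
  beta <- as.matrix(bank[paste0("beta_", 1:3)])
  expect_equal(colMeans(beta), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  # shifts are exactly +/-0.5, half each (even item count)
  for (g in 2:3) {
    shifts <- beta[, g] - beta[, 1]
    expect_setequal(round(unique(shifts), 10), c(0.5, -0.5))
    expect_equal(sum(shifts > 0), 10)
  }
  # fixed threshold grid on every item
  expect_true(all(bank$tau_1 == -0.6 & bank$tau_2 == 0 & bank$tau_3 == 0.6))
  # odd item count: still centered
  d2 <- sim_design(n_items = 13, seed = 4)
  set.seed(4)
  bank2 <- sim_item_bank(d2)
  expect_equal(mean(bank2$beta_2), 0, tolerance = 1e-12)
})

test_that("CD item banks respect the MDP split", {
  d <- sim_design(n_items = 40, mdp = 1.5, seed = 8)
  set.seed(8)
  bank <- sim_item_bank(d)
  expect_true(all(bank$alpha1 < 1.5))
  expect_equal(bank$alpha1^2 + bank$alpha2^2, rep(1.5^2, 40),
               tolerance = 1e-12)
})

test_that("person generation follows the class structure", {
  d <- sim_design(n_respondents = 2000, seed = 11)
  set.seed(11)
  p <- sim_persons(d)
  expect_true(all(p$omega[p$class == 1] == 1))
  expect_true(all(p$omega[p$class != 1] != 1))
  # multinomial class counts within 4 SD of expectation at N = 2000
  counts <- table(factor(p$class, levels = 1:3))
  expe <- 2000 * d$class_proportions
  sds <- sqrt(2000 * d$class_proportions * (1 - d$class_proportions))
  expect_true(all(abs(counts - expe) < 4 * sds))
  # theta standard normal in every class
  for (g in 1:3) {
    expect_equal(mean(p$theta[p$class == g]), 0, tolerance = 0.2)
    expect_equal(sd(p$theta[p$class == g]), 1, tolerance = 0.15)
  }
})

test_that("the ERS-class omega interval reproduces the design's two-SD
          bounds", {
  d <- sim_design()
  expect_equal(round(omega_central_interval(d, class = 2), 2),
               c(0.17, 0.82))
  set.seed(21)
  p <- sim_persons(sim_design(n_respondents = 20000, seed = 21))
  om <- p$omega[p$class == 2]
  expect_equal(mean(om >= 0.165 & om <= 0.819), 0.954, tolerance = 0.01)
})

test_that("response simulation is deterministic and respects the range", {
  d <- sim_design(n_respondents = 150, n_items = 8, seed = 5)
  s1 <- simulate_study(d)
  s2 <- simulate_study(d)
  expect_identical(s1$responses, s2$responses)
  Y <- as.matrix(s1$responses[paste0("item_", 1:8)])
  expect_true(all(Y >= 1 & Y <= 4))
  expect_identical(s1$items, s2$items)
  # attached truth reproduces the generating inputs
  expect_identical(nrow(s1$persons), 150L)
})

test_that("single-cell response frequencies match the model probabilities", {
  # 1e5 iid draws from one (person, item) cell vs the closed form
  bank <- item_bank(alpha1 = 1.1, beta = matrix(0, 1, 3),
                    tau = matrix(c(-0.6, 0, 0.6), 1))
  # off-center difficulties (identification only applies within a test)
  bank$beta_1 <- 0.2; bank$beta_2 <- -0.3; bank$beta_3 <- 0.1
  persons <- tibble::tibble(person = 1:100000, class = 2L, label = "ERS",
                            theta = 0.7, omega = 0.45)
  sim <- sim_responses(bank, persons, model = "mix-ers-gpcm",
                       n_categories = 4, seed = 31)
  p_model <- mixture_ers_gpcm_probs(0.7, 0.45, bank, 1, 2)
  freq <- tabulate(sim$responses$item_1, nbins = 4) / 100000
  se <- sqrt(p_model * (1 - p_model) / 100000)
  expect_true(all(abs(freq - p_model) <= 3 * se + 1e-9))
})

test_that("ERS respondents endorse extreme categories more than matched
          normal respondents", {
  d <- sim_design(n_respondents = 4000, n_items = 20, seed = 17)
  sim <- simulate_study(d)
  Y <- as.matrix(sim$responses[paste0("item_", 1:20)])
  extreme <- rowMeans(Y == 1 | Y == 4)
  cls <- sim$persons$class
  expect_gt(mean(extreme[cls == 2]), mean(extreme[cls == 1]) + 0.1)
  # MRS respondents avoid the endpoints
  expect_lt(mean(extreme[cls == 3]), mean(extreme[cls == 1]) - 0.05)
})

test_that("CD generation dampens style effects on low-alpha2 items", {
  # two items identical except for alpha2; ERS (omega = 0.4) vs normal
  bank <- item_bank(alpha1 = c(1, 1), beta = matrix(0, 2, 2),
                    tau = c(-0.6, 0, 0.6), alpha2 = c(0.1, 1.3))
  persons <- tibble::tibble(person = 1:6000,
                            class = rep(1:2, each = 3000),
                            label = rep(c("normal", "ERS"), each = 3000),
                            theta = 0, omega = rep(c(1, 0.4), each = 3000))
  sim_cd <- sim_responses(bank, persons, model = "mix-ers-gpcm-cd",
                          n_categories = 4, seed = 1)
  Y <- as.matrix(sim_cd$responses[paste0("item_", 1:2)])
  gap <- function(i) {
    ex <- Y[, i] == 1 | Y[, i] == 4
    mean(ex[persons$class == 2]) - mean(ex[persons$class == 1])
  }
  expect_gt(gap(2), gap(1) + 0.05)
})
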