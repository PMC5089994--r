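# Brute-force adjacent-category oracle: exponentiate cumulative sums of the
# adjacent log-odds and normalize.  Written independently of the package's
# log-sum-exp implementation.
oracle_probs <- function(theta, alpha, beta, tau, weight = 1) {
  J <- length(tau) + 1
  cum <- numeric(J)
  for (j in 2:J) {
    cum[j] <- cum[j - 1] + alpha * theta - (beta + weight * tau[j - 1])
  }
  e <- exp(cum)
  e / sum(e)
}

# small simulated data set reused across estimation tests
tiny_mix_sim <- function(seed = 42, N = 600, I = 16) {
  d <- sim_design(n_respondents = N, n_items = I, n_categories = 4,
                  seed = seed)
  simulate_study(d)
}

quiet_fit <- function(...) suppressWarnings(fit_ersmix(...))
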