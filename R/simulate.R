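# Simulation designs and response generation for recovery studies.

default_tau_grid <- function(J) {
  # symmetric, zero-mean step grids used in the recovery studies
  if (J == 4L) return(c(-0.6, 0, 0.6))
  if (J == 6L) return(c(-0.8, -0.4, 0, 0.4, 0.8))
  g <- seq(-0.6, 0.6, length.out = J - 1L)
  g - mean(g)
}

#' Define a simulation design
#'
#' Defaults reproduce the conditions of the recovery studies: three latent
#' classes (normal/ERS/MRS) with proportions 0.50/0.25/0.25; theta ~ N(0,1)
#' in every class; omega fixed at 1 in the normal class and drawn from
#' lognormal(-1, 0.4^2) (ERS) and lognormal(1, 0.4^2) (MRS); item
#' discriminations lognormal(meanlog = 0, sdlog = 0.2); normal-class
#' difficulties uniform on (-1.5, 1.5) centered to mean zero; style-class
#' difficulties shifted by a balanced +/-0.5; fixed symmetric threshold
#' grids (-0.6, 0, 0.6) for 4 categories and (-0.8, -0.4, 0, 0.4, 0.8) for
#' 6.  Setting `mdp` (1.5 in the CD study) switches on the
#' constrained-discrimination item structure with `alpha2` derived from
#' `alpha1` via [alpha2_from_mdp()].
#'
#' @param n_respondents Number of respondents N.
#' @param n_items Number of items I.
#' @param n_categories Number of ordered categories J.
#' @param class_proportions Mixing proportions, normal class first and
#'   dominant.
#' @param omega_meanlog,omega_sdlog Per-class lognormal parameters for
#'   omega; the first (normal) entry is ignored (omega = 1).
#' @param alpha1_meanlog,alpha1_sdlog Lognormal parameters for the
#'   target-trait discriminations.
#' @param beta_range Range of the uniform normal-class difficulty draw.
#' @param class_beta_shift Absolute difficulty shift applied to the style
#'   classes with a balanced random sign assignment (half the items +shift,
#'   half -shift), so every class keeps mean difficulty zero.
#' @param tau_grid Step-threshold grid (zero-mean, length J - 1);
#'   `NULL` picks the default grid for J.
#' @param mdp Optional total discrimination (per subscale) for CD designs.
#' @param n_subscales Number of subscales; items are split evenly.
#' @param theta_cov Optional S x S covariance matrix for multidimensional
#'   traits (defaults to the identity).
#' @param seed Integer seed for all randomness in the design's draws.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_respondents = 1000L, n_items = 20L,
                       n_categories = 4L,
                       class_proportions = c(0.50, 0.25, 0.25),
                       omega_meanlog = c(0, -1, 1),
                       omega_sdlog = c(0, 0.4, 0.4),
                       alpha1_meanlog = 0, alpha1_sdlog = 0.2,
                       beta_range = c(-1.5, 1.5),
                       class_beta_shift = 0.5,
                       tau_grid = NULL,
                       mdp = NULL, n_subscales = 1L, theta_cov = NULL,
                       seed = 1L) {
  G <- length(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("`class_proportions` must sum to one.", call. = FALSE)
  }
  if (G > 1L && class_proportions[1] < max(class_proportions[-1])) {
    stop("the normal class (first entry) must have the dominant proportion.",
         call. = FALSE)
  }
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(as.integer(n_categories))
  if (length(tau_grid) != n_categories - 1L) {
    stop("`tau_grid` must have length `n_categories` - 1.", call. = FALSE)
  }
  if (abs(mean(tau_grid)) > 1e-8) {
    stop("`tau_grid` must have mean zero.", call. = FALSE)
  }
  omega_meanlog <- rep_len(omega_meanlog, G)
  omega_sdlog <- rep_len(omega_sdlog, G)
  if (!is.null(theta_cov)) {
    theta_cov <- as.matrix(theta_cov)
    if (nrow(theta_cov) != n_subscales) {
      stop("`theta_cov` must be `n_subscales` x `n_subscales`.",
           call. = FALSE)
    }
  }
  structure(
    list(n_respondents = as.integer(n_respondents),
         n_items = as.integer(n_items),
         n_categories = as.integer(n_categories),
         class_proportions = class_proportions,
         omega_meanlog = omega_meanlog, omega_sdlog = omega_sdlog,
         alpha1_meanlog = alpha1_meanlog, alpha1_sdlog = alpha1_sdlog,
         beta_range = beta_range, class_beta_shift = class_beta_shift,
         tau_grid = tau_grid, mdp = mdp,
         n_subscales = as.integer(n_subscales), theta_cov = theta_cov,
         seed = as.integer(seed)),
    class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design> N =", x$n_respondents, "| items =", x$n_items,
      "| categories =", x$n_categories,
      "| classes =", length(x$class_proportions),
      if (!is.null(x$mdp)) paste("| MDP =", x$mdp), "\n")
  invisible(x)
}

# Balanced +/-shift assignment: half the items get +shift, half -shift
# (random assignment); with an odd item count the extra sign is drawn and
# the shifted difficulties are re-centered so the class mean stays zero.
balanced_shift <- function(I, shift) {
  half <- I %/% 2L
  signs <- c(rep(1, half), rep(-1, half))
  if (I %% 2L == 1L) signs <- c(signs, sample(c(-1, 1), 1L))
  s <- sample(signs) * shift
  s - mean(s)
}

#' Generate an item bank from a simulation design
#'
#' Draws discriminations from the design's lognormal, normal-class
#' difficulties from the centered uniform, applies the balanced class
#' difficulty shifts, fixes every item's thresholds at the design grid, and
#' (for CD designs) derives `alpha2` from the MDP.  Discrimination draws
#' exceeding the MDP are redrawn so the split `alpha1^2 + alpha2^2 = mdp^2`
#' stays feasible.
#'
#' @param design A [sim_design()].
#' @return An `ers_item_bank` tibble (see [item_bank()]).
#' @export
sim_item_bank <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  I <- design$n_items
  G <- length(design$class_proportions)
  alpha1 <- rlnorm(I, design$alpha1_meanlog, design$alpha1_sdlog)
  if (!is.null(design$mdp)) {
    while (any(bad <- alpha1 >= design$mdp)) {
      alpha1[bad] <- rlnorm(sum(bad), design$alpha1_meanlog,
                            design$alpha1_sdlog)
    }
  }
  beta_n <- runif(I, design$beta_range[1], design$beta_range[2])
  beta_n <- beta_n - mean(beta_n)
  beta <- matrix(beta_n, nrow = I, ncol = G)
  if (G > 1L) {
    for (g in 2:G) {
      beta[, g] <- beta_n + balanced_shift(I, design$class_beta_shift)
    }
  }
  subscale <- rep(seq_len(design$n_subscales), length.out = I)
  subscale <- sort(subscale)
  item_bank(alpha1 = alpha1, beta = beta,
            tau = matrix(design$tau_grid, I, design$n_categories - 1L,
                         byrow = TRUE),
            mdp = design$mdp, subscale = subscale)
}

#' Generate person states from a simulation design
#'
#' Class labels are multinomial with the design proportions; theta is
#' standard normal in every class (multivariate normal with `theta_cov`
#' for multidimensional designs); omega is exactly one in the normal class
#' and lognormal in the style classes.
#'
#' @param design A [sim_design()].
#' @return A tibble with columns `person`, `class`, `label`,
#'   `theta` (or `theta_1..theta_S`) and `omega`.
#' @export
sim_persons <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  N <- design$n_respondents
  G <- length(design$class_proportions)
  cls <- sample.int(G, N, replace = TRUE, prob = design$class_proportions)
  S <- design$n_subscales
  if (S == 1L) {
    theta <- matrix(rnorm(N), ncol = 1L)
  } else {
    Sig <- if (is.null(design$theta_cov)) diag(S) else design$theta_cov
    theta <- MASS::mvrnorm(N, mu = rep(0, S), Sigma = Sig)
  }
  omega <- rep(1, N)
  if (G > 1L) {
    for (g in 2:G) {
      idx <- cls == g
      omega[idx] <- rlnorm(sum(idx), design$omega_meanlog[g],
                           design$omega_sdlog[g])
    }
  }
  out <- tibble::tibble(person = seq_len(N), class = as.integer(cls),
                        label = class_labels(G)[cls])
  if (S == 1L) out$theta <- theta[, 1L]
  else for (s in seq_len(S)) out[[paste0("theta_", s)]] <- theta[, s]
  out$omega <- omega
  out
}

class_labels <- function(G) {
  switch(as.character(G),
         "1" = "normal",
         "2" = c("normal", "style"),
         "3" = c("normal", "ERS", "MRS"),
         as.character(seq_len(G)))
}

# N x S theta matrix from a persons tibble
theta_matrix <- function(persons) {
  cols <- grep("^theta(_[0-9]+)?$", names(persons), value = TRUE)
  as.matrix(persons[cols])
}

#' Simulate a response matrix
#'
#' Draws each response from the category-probability vector of the chosen
#' model at the supplied true item and person parameters.  The truth is
#' attached so recovery metrics can be computed later.
#'
#' @param items An item bank (see [sim_item_bank()]).
#' @param persons A persons tibble (see [sim_persons()]).
#' @param model Generating model: `"mix-ers-gpcm"` (threshold weight
#'   omega itself) or `"mix-ers-gpcm-cd"` (effective weight
#'   `omega^alpha2`); multidimensional forms are inferred from the theta
#'   columns.
#' @param n_categories Number of response categories J.
#' @param seed Optional integer seed (set just before the draws).
#' @return An object of class `ers_sim`: list with `responses` (tibble,
#'   categories coded `1..J`), `items`, `persons`, `model`,
#'   `n_categories`.
#' @export
sim_responses <- function(items, persons, model = "mix-ers-gpcm",
                          n_categories, seed = NULL) {
  model <- match.arg(model, c("mix-ers-gpcm", "mix-ers-gpcm-cd",
                              "gpcm", "ers-gpcm"))
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(persons)
  I <- nrow(items)
  J <- as.integer(n_categories)
  theta <- theta_matrix(persons)
  cls <- if ("class" %in% names(persons)) persons$class else rep(1L, N)
  omega <- if ("omega" %in% names(persons)) persons$omega else rep(1, N)
  logw <- ifelse(cls == 1L & model != "ers-gpcm", 0, log(omega))
  if (model == "gpcm") logw <- rep(0, N)
  alpha2 <- sim_alpha2(items, model)
  tau <- tau_matrix(items)
  if (ncol(tau) != J - 1L) {
    stop("item bank thresholds do not match `n_categories`.", call. = FALSE)
  }
  beta <- beta_matrix(items)
  Y <- matrix(0L, N, I)
  for (i in seq_len(I)) {
    lin <- items$alpha1[i] * theta[, items$subscale[i]]
    w <- exp(alpha2[i] * logw)
    # cumulative adjacent log-odds for all persons at once
    cum <- matrix(0, N, J)
    for (j in seq_len(J - 1L)) {
      cum[, j + 1L] <- cum[, j] + lin - beta[cbind(i, cls)] - w * tau[i, j]
    }
    cum <- cum - apply(cum, 1L, max)
    p <- exp(cum)
    p <- p / rowSums(p)
    u <- runif(N)
    Y[, i] <- as.integer(rowSums(u > t(apply(p, 1L, cumsum))) )
  }
  responses <- tibble::as_tibble(as.data.frame(Y + 1L),
                                 .name_repair = "minimal")
  names(responses) <- paste0("item_", seq_len(I))
  responses <- dplyr::bind_cols(
    tibble::tibble(person = seq_len(N)), responses)
  structure(list(responses = responses, items = items, persons = persons,
                 model = model, n_categories = J),
            class = "ers_sim")
}

# per-item discrimination on the style dimension used when generating
sim_alpha2 <- function(items, model) {
  if (grepl("cd", model)) {
    a2 <- items$alpha2
    if (any(is.na(a2))) {
      if (all(is.na(items$mdp))) {
        stop("CD generation needs `alpha2` or `mdp` in the item bank.",
             call. = FALSE)
      }
      a2 <- alpha2_from_mdp(items$mdp, items$alpha1)
    }
    a2
  } else {
    rep(1, nrow(items))
  }
}

#' @export
print.ers_sim <- function(x, ...) {
  cat("<ers_sim>", nrow(x$responses), "persons x", nrow(x$items),
      "items,", x$n_categories, "categories, model", x$model, "\n")
  invisible(x)
}

#' Simulate a full recovery-study data set in one call
#'
#' Convenience wrapper: seeds the RNG, draws the item bank and persons from
#' the design, and simulates responses.
#'
#' @param design A [sim_design()].
#' @param model Generating model passed to [sim_responses()].
#' @return An `ers_sim` object.
#' @export
simulate_study <- function(design, model = "mix-ers-gpcm") {
  set.seed(design$seed)
  items <- sim_item_bank(design)
  persons <- sim_persons(design)
  sim_responses(items, persons, model = model,
                n_categories = design$n_categories)
}

#' Central lognormal interval for a style class's omega distribution
#'
#' Returns `exp(meanlog +/- k * sdlog)`, the central interval covering
#' `2*pnorm(k)-1` of the class's omega distribution (k = 2: about 95.4%).
#'
#' @param design A [sim_design()].
#' @param class Class index (2 = ERS, 3 = MRS under the default design).
#' @param k Half-width in standard deviations on the log scale.
#' @return Length-2 numeric vector (lower, upper).
#' @export
omega_central_interval <- function(design, class = 2L, k = 2) {
  stopifnot(inherits(design, "sim_design"), class >= 2L,
            class <= length(design$class_proportions))
  exp(design$omega_meanlog[class] + c(-1, 1) * k * design$omega_sdlog[class])
}
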