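# Category-probability functions for the ERS-GPCM model family.
#
# All models share the adjacent-category logit kernel
#   log(P_j / P_{j-1}) = a * theta - (b + w * tau_j),    j = 1, ..., J-1,
# with categories scored 0..J-1 internally (the baseline category has no
# threshold).  Probabilities are obtained by cumulating the adjacent
# log-odds and normalizing with log-sum-exp.

# Cumulative adjacent-logit -> probability vector, log-sum-exp normalized.
adjacent_logit_probs <- function(logits) {
  cum <- c(0, cumsum(logits))
  cum <- cum - max(cum)
  e <- exp(cum)
  e / sum(e)
}

check_tau <- function(tau) {
  if (length(tau) < 1L) {
    stop("`tau` must contain at least one threshold (J >= 2).", call. = FALSE)
  }
  if (anyNA(tau)) stop("`tau` must not contain missing values.", call. = FALSE)
  invisible(tau)
}

#' Category probabilities under the generalized partial credit model
#'
#' Computes the probability of each ordered response category `0..J-1` for a
#' single person-item encounter under the GPCM, in which the log-odds of
#' scoring `j` rather than `j - 1` equal `alpha * theta - (beta + tau[j])`.
#'
#' @param theta Latent trait value.
#' @param alpha Item discrimination (positive).
#' @param beta Overall item difficulty.
#' @param tau Numeric vector of `J - 1` step thresholds.
#' @return A numeric probability vector of length `J` (sums to one).
#' @examples
#' gpcm_category_probs(theta = 1, alpha = 1, beta = 0, tau = c(-0.6, 0, 0.6))
#' @seealso [ers_gpcm_probs()] for the response-style weighted extension.
#' @export
gpcm_category_probs <- function(theta, alpha, beta, tau) {
  check_tau(tau)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a positive discrimination.", call. = FALSE)
  }
  adjacent_logit_probs(alpha * theta - (beta + tau))
}

#' Category probabilities under the ERS-GPCM
#'
#' Extends the GPCM with a person-level threshold weight `omega` that
#' contracts (`omega < 1`, extreme response style) or expands (`omega > 1`,
#' mild response style) the rating scale:
#' `log(P_j/P_{j-1}) = alpha * theta - (beta + omega * tau[j])`.
#' With `omega = 1` the model reduces exactly to the GPCM.
#'
#' @inheritParams gpcm_category_probs
#' @param omega Positive person-level threshold weight.
#' @return A numeric probability vector of length `J`.
#' @export
ers_gpcm_probs <- function(theta, alpha, beta, tau, omega) {
  if (!is.finite(omega) || omega <= 0) {
    stop("`omega` must be positive.", call. = FALSE)
  }
  gpcm_category_probs(theta, alpha, beta, omega * tau)
}

#' Effective threshold weight in the constrained-discrimination model
#'
#' In the CD variant each item carries its own discrimination `alpha2` on the
#' response-style dimension, and the person weight `omega` acts on an item's
#' thresholds through `eta = exp(alpha2 * log(omega)) = omega^alpha2`.
#' Items with `alpha2` near zero are insensitive to response style
#' (`eta` near 1 for every omega).
#'
#' @param omega Positive person-level threshold weight (vectorized).
#' @param alpha2 Non-negative item discrimination on the style dimension
#'   (vectorized).
#' @return `omega ^ alpha2`, recycled to the common length.
#' @examples
#' eta_weight(c(0.5, 1, 1.5), 0.2)  # 0.87, 1.00, 1.08 to two decimals
#' @export
eta_weight <- function(omega, alpha2) {
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("`omega` must be positive.", call. = FALSE)
  }
  if (any(!is.finite(alpha2)) || any(alpha2 < 0)) {
    stop("`alpha2` must be non-negative.", call. = FALSE)
  }
  exp(alpha2 * log(omega))
}

#' Split a fixed multidimensional discrimination between dimensions
#'
#' The CD models fix the total discriminating power of an item at `mdp` and
#' apportion it between the target trait (`alpha1`) and the style dimension
#' (`alpha2`) on a circle: `alpha1^2 + alpha2^2 = mdp^2`.  Given `mdp` and
#' `alpha1`, returns `alpha2 = sqrt(mdp^2 - alpha1^2)`.
#'
#' @param mdp Positive total (multidimensional) discrimination.
#' @param alpha1 Positive discrimination on the target trait; must not
#'   exceed `mdp`.
#' @return Non-negative `alpha2`, vectorized over the inputs.
#' @examples
#' alpha2_from_mdp(1.5, 0.9)  # 1.2
#' @export
alpha2_from_mdp <- function(mdp, alpha1) {
  if (any(!is.finite(mdp)) || any(mdp <= 0)) {
    stop("`mdp` must be positive.", call. = FALSE)
  }
  if (any(!is.finite(alpha1)) || any(alpha1 <= 0)) {
    stop("`alpha1` must be positive.", call. = FALSE)
  }
  if (any(alpha1 > mdp)) {
    stop("`alpha1` must not exceed `mdp` (alpha1^2 + alpha2^2 = mdp^2).",
         call. = FALSE)
  }
  sqrt(mdp^2 - alpha1^2)
}

item_row <- function(item_bank, item) {
  if (!is.numeric(item) || length(item) != 1L || item < 1 ||
      item > nrow(item_bank)) {
    stop("`item` must index a row of `item_bank`.", call. = FALSE)
  }
  item_bank[item, , drop = FALSE]
}

item_beta <- function(row, class) {
  col <- paste0("beta_", class)
  if (!col %in% names(row)) {
    stop("item bank has no class-specific difficulty column `", col, "`.",
         call. = FALSE)
  }
  row[[col]]
}

item_tau <- function(row) {
  cols <- grep("^tau_", names(row), value = TRUE)
  check_tau(unlist(row[cols], use.names = FALSE))
}

#' Category probabilities under the mixture ERS-GPCM
#'
#' Class `g` has its own overall item difficulty `beta_g` (class columns
#' `beta_1`, `beta_2`, ... of the item bank); the normal class (`class = 1`)
#' has `omega` fixed at one.
#'
#' @param theta Latent trait value of the respondent.
#' @param omega Positive threshold weight of the respondent; ignored (forced
#'   to 1) for the normal class.
#' @param item_bank An item-parameter tibble as built by [item_bank()] or
#'   [sim_item_bank()].
#' @param item Row index of the item.
#' @param class Latent class index (1 = normal).
#' @return A numeric probability vector of length `J`.
#' @export
mixture_ers_gpcm_probs <- function(theta, omega, item_bank, item, class) {
  row <- item_row(item_bank, item)
  w <- if (class == 1L) 1 else omega
  ers_gpcm_probs(theta, row$alpha1, item_beta(row, class), item_tau(row), w)
}

#' Category probabilities under the mixture ERS-GPCM-CD
#'
#' The constrained-discrimination variant replaces the raw person weight by
#' the item-specific effective weight `eta = omega^alpha2`
#' (see [eta_weight()]); `alpha2` is taken from the item bank, or derived
#' from `mdp` via [alpha2_from_mdp()] when absent.
#'
#' @inheritParams mixture_ers_gpcm_probs
#' @return A numeric probability vector of length `J`.
#' @export
cd_model_probs <- function(theta, omega, item_bank, item, class) {
  row <- item_row(item_bank, item)
  a2 <- row$alpha2
  if (is.null(a2) || is.na(a2)) {
    if (is.null(row$mdp) || is.na(row$mdp)) {
      stop("item bank provides neither `alpha2` nor `mdp`.", call. = FALSE)
    }
    a2 <- alpha2_from_mdp(row$mdp, row$alpha1)
  }
  w <- if (class == 1L) 1 else omega
  ers_gpcm_probs(theta, row$alpha1, item_beta(row, class), item_tau(row),
                 eta_weight(w, a2))
}

#' Category probabilities under the multidimensional CD model
#'
#' Each item loads on the single subscale recorded in the item bank's
#' `subscale` column, so its probabilities depend only on that component of
#' the latent trait vector.  A single common `omega` per respondent is
#' shared across subscales.  With one subscale this reproduces
#' [cd_model_probs()] exactly.
#'
#' @param theta Numeric latent-trait vector, one entry per subscale.
#' @inheritParams mixture_ers_gpcm_probs
#' @return A numeric probability vector of length `J`.
#' @export
multidim_cd_probs <- function(theta, omega, item_bank, item, class) {
  row <- item_row(item_bank, item)
  s <- row$subscale
  if (is.null(s) || is.na(s)) {
    stop("item ", item, " has no subscale assignment.", call. = FALSE)
  }
  if (s < 1 || s > length(theta)) {
    stop("`theta` has no component for subscale ", s, ".", call. = FALSE)
  }
  cd_model_probs(theta[[s]], omega, item_bank, item, class)
}
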