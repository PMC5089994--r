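# Model specifications and item-parameter containers.

ers_model_names <- c("gpcm", "ers-gpcm", "mix-ers-gpcm", "mix-ers-gpcm-cd",
                     "mix-ers-gpcm-multidim", "mix-ers-gpcm-cd-multidim")

#' Specify a model from the ERS-GPCM family
#'
#' @param model One of `"gpcm"`, `"ers-gpcm"`, `"mix-ers-gpcm"`,
#'   `"mix-ers-gpcm-cd"`, or their `"-multidim"` variants.
#' @param n_classes Number of latent classes `G` (forced to 1 for
#'   `"gpcm"`/`"ers-gpcm"`).  Class 1 is always the normal class
#'   (theta ~ N(0,1), omega = 1); further classes are response-style
#'   classes ordered ERS before MRS.
#' @param n_categories Number of ordered response categories `J`.
#' @param restriction Optional submodel restriction: `"GRSM"` (common
#'   thresholds across items), `"PCM"` (all discriminations fixed at 1) or
#'   `"RSM"` (both).  See [restrict_model()].
#' @param n_subscales Number of subscales `S` for multidimensional models.
#' @param equal_alpha_classes Keep discriminations invariant across latent
#'   classes (the default, giving metric invariance); kept for interface
#'   completeness.
#' @return An object of class `ers_model_spec`.
#' @export
ers_model_spec <- function(model = "mix-ers-gpcm", n_classes = 3L,
                           n_categories = 4L, restriction = NULL,
                           n_subscales = 1L, equal_alpha_classes = TRUE) {
  model <- match.arg(model, ers_model_names)
  if (model %in% c("gpcm", "ers-gpcm")) n_classes <- 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L || n_classes > 3L) {
    stop("`n_classes` must be 1, 2 or 3.", call. = FALSE)
  }
  if (n_categories < 2L) stop("`n_categories` must be >= 2.", call. = FALSE)
  if (!grepl("multidim", model)) n_subscales <- 1L
  spec <- structure(
    list(model = model,
         cd = grepl("cd", model),
         multidim = grepl("multidim", model),
         n_classes = n_classes,
         n_categories = as.integer(n_categories),
         n_subscales = as.integer(n_subscales),
         restriction = NULL,
         equal_alpha_classes = isTRUE(equal_alpha_classes)),
    class = "ers_model_spec")
  if (!is.null(restriction)) spec <- restrict_model(spec, restriction)
  spec
}

#' Restrict a model to a rating-scale submodel
#'
#' `"GRSM"` ties the step thresholds across items (one common tau vector),
#' `"PCM"` fixes every discrimination at one, and `"RSM"` applies both.
#' Restrictions compose idempotently and order-independently, so
#' `RSM = PCM o GRSM`.
#'
#' When applied to an item bank (a tibble with `alpha1` and `tau_*`
#' columns) the restriction is enforced directly: GRSM replaces each item's
#' thresholds by the across-item mean vector (re-centered to sum zero) and
#' PCM sets `alpha1 = 1`.
#'
#' @param spec An [ers_model_spec()] or an item-bank tibble.
#' @param restriction `"GRSM"`, `"PCM"` or `"RSM"`.
#' @return An object of the same type as `spec`.
#' @export
restrict_model <- function(spec, restriction) {
  restriction <- match.arg(toupper(restriction), c("GRSM", "PCM", "RSM"))
  if (inherits(spec, "ers_model_spec")) {
    prev <- spec$restriction
    parts <- unique(c(
      if (!is.null(prev)) if (prev == "RSM") c("GRSM", "PCM") else prev,
      if (restriction == "RSM") c("GRSM", "PCM") else restriction))
    spec$restriction <- if (all(c("GRSM", "PCM") %in% parts)) "RSM"
                        else parts
    return(spec)
  }
  if (!is.data.frame(spec)) {
    stop("`spec` must be an `ers_model_spec` or an item-bank tibble.",
         call. = FALSE)
  }
  bank <- spec
  if (restriction %in% c("GRSM", "RSM")) {
    tau_cols <- grep("^tau_", names(bank), value = TRUE)
    common <- colMeans(bank[tau_cols])
    common <- common - mean(common)
    for (k in seq_along(tau_cols)) bank[[tau_cols[k]]] <- common[[k]]
  }
  if (restriction %in% c("PCM", "RSM")) bank$alpha1 <- 1
  bank
}

#' Build an item-parameter bank
#'
#' One row per item, with the class-specific overall difficulties in
#' columns `beta_1 .. beta_G` and the `J - 1` step thresholds in columns
#' `tau_1 .. tau_{J-1}`.  Within each class the mean difficulty over items
#' should be zero (the common-metric identification used for latent-DIF
#' comparisons); this is checked up to `tol`.
#'
#' @param alpha1 Positive discriminations on the target trait (length I).
#' @param beta Matrix (I x G) or vector (G = 1) of overall difficulties.
#' @param tau Matrix (I x (J-1)) or single vector of step thresholds.
#' @param alpha2 Optional non-negative discriminations on the style
#'   dimension (CD models).
#' @param mdp Optional total discrimination per subscale; when given and
#'   `alpha2` is absent, `alpha2` is derived via [alpha2_from_mdp()].
#' @param subscale Integer subscale assignment per item (default all 1).
#' @param tol Tolerance for the per-class mean-zero difficulty check.
#' @return A tibble of class `ers_item_bank`.
#' @export
item_bank <- function(alpha1, beta, tau, alpha2 = NULL, mdp = NULL,
                      subscale = NULL, tol = 1e-8) {
  I <- length(alpha1)
  if (any(alpha1 <= 0)) stop("`alpha1` must be positive.", call. = FALSE)
  beta <- as.matrix(beta)
  if (nrow(beta) != I) stop("`beta` must have one row per item.", call. = FALSE)
  off <- abs(colMeans(beta))
  if (any(off > tol)) {
    stop("per-class mean item difficulty must be zero (max |mean| = ",
         signif(max(off), 3), ").", call. = FALSE)
  }
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = I, ncol = length(tau),
                                       byrow = TRUE)
  if (nrow(tau) != I) stop("`tau` must have one row per item.", call. = FALSE)
  if (is.null(subscale)) subscale <- rep(1L, I)
  mdp_s <- if (is.null(mdp)) NA_real_ else rep_len(mdp, max(subscale))
  if (is.null(alpha2) && !is.null(mdp)) {
    alpha2 <- alpha2_from_mdp(mdp_s[subscale], alpha1)
  }
  if (!is.null(alpha2) && any(alpha2 < 0)) {
    stop("`alpha2` must be non-negative.", call. = FALSE)
  }
  out <- tibble::tibble(item = seq_len(I), subscale = as.integer(subscale),
                        alpha1 = as.numeric(alpha1))
  out$alpha2 <- if (is.null(alpha2)) NA_real_ else as.numeric(alpha2)
  out$mdp <- if (is.null(mdp)) NA_real_ else mdp_s[out$subscale]
  for (g in seq_len(ncol(beta))) out[[paste0("beta_", g)]] <- beta[, g]
  for (j in seq_len(ncol(tau))) out[[paste0("tau_", j)]] <- tau[, j]
  class(out) <- c("ers_item_bank", class(out))
  out
}

# Extract the I x (J-1) threshold matrix from an item bank.
tau_matrix <- function(bank) {
  as.matrix(bank[grep("^tau_", names(bank), value = TRUE)])
}

# Extract the I x G difficulty matrix from an item bank.
beta_matrix <- function(bank) {
  as.matrix(bank[grep("^beta_", names(bank), value = TRUE)])
}
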