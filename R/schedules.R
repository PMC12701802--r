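# Training schedules and elementary model operations.  These are the
# analytic pieces of the fitting procedure; each is exported so the
# schedules can be replayed and audited outside the training loop.

#' Advance the activity-blending coefficient
#'
#' `alpha` controls the convex combination between prior-driven ULM
#' activities and the decoder's data-driven activities; it increases in
#' steps of `delta_alpha` and saturates at `alpha_max`.
#'
#' @param alpha current value in `[0, 1]`.
#' @param delta_alpha step size.
#' @param alpha_max ceiling.
#' @return `min(alpha_max, alpha + delta_alpha)`.
#' @export
alpha_step <- function(alpha, delta_alpha, alpha_max) {
  stopifnot(alpha >= 0, alpha <= 1, delta_alpha >= 0, alpha_max <= 1)
  min(alpha_max, alpha + delta_alpha)
}

#' Linearly ramped L1 coefficient
#'
#' The GRN sparsity penalty ramps linearly from 0 at epoch 0 to
#' `gamma_max` at epoch `T`, so early training follows the prior before
#' sparsification bites.
#'
#' @param t current epoch (0..T).
#' @param T total epochs (> 0).
#' @param gamma_max terminal value.
#' @return `gamma_max * t / T`.
#' @export
gamma_schedule <- function(t, T, gamma_max) {
  if (T <= 0) stop("T must be positive")
  stopifnot(t >= 0, t <= T, gamma_max >= 0)
  gamma_max * t / T
}

#' Prior-mask factor
#'
#' Logistic schedule blending the GRN weight matrix with the prior: it
#' starts at ~1 (prior enforced) and decays to ~0 (weights fully
#' learned), crossing 0.5 at mid-training with a transition width of
#' `T/20` epochs.  `increasing = TRUE` gives the mirrored (rising)
#' logistic.
#'
#' @param t epoch.
#' @param T total epochs (> 0).
#' @param increasing use the rising variant (default `FALSE`).
#' @return value in (0, 1).
#' @export
mask_factor <- function(t, T, increasing = FALSE) {
  if (T <= 0) stop("T must be positive")
  s <- (t - T / 2) / (T / 20)
  if (increasing) s <- -s
  1 / (1 + exp(s))
}

#' Blend ULM and decoder TF activities
#'
#' @param e_ulm,e_dec equal-shape non-negative activity vectors or
#'   matrices.
#' @param alpha blending coefficient in `[0, 1]`.
#' @return `(1 - alpha) * e_ulm + alpha * e_dec`.
#' @export
blend_activities <- function(e_ulm, e_dec, alpha) {
  stopifnot(length(e_ulm) == length(e_dec), alpha >= 0, alpha <= 1)
  (1 - alpha) * e_ulm + alpha * e_dec
}

#' Blend GRN weights with the prior
#'
#' Applied once per epoch after the optimizer step:
#' `W <- m * W_prior + (1 - m) * W`.
#'
#' @param W_prev current TF-by-gene weights.
#' @param W_prior frozen prior weights (same shape).
#' @param m mask factor in `[0, 1]`.
#' @return blended matrix.
#' @export
blend_grn <- function(W_prev, W_prior, m) {
  if (!all(dim(W_prev) == dim(W_prior)))
    stop("W_prev and W_prior must have the same shape")
  stopifnot(m >= 0, m <= 1)
  m * W_prior + (1 - m) * W_prev
}

#' L1 penalty on the GRN weight matrix
#'
#' @param W TF-by-gene matrix.
#' @param gamma non-negative coefficient.
#' @return `gamma * sum(abs(W))`.
#' @export
grn_l1_loss <- function(W, gamma) {
  stopifnot(gamma >= 0)
  gamma * sum(abs(W))
}

#' Reparameterization of the latent draw
#'
#' @param mu,sigma,eps equal-shape vectors/matrices; `sigma >= 0`.
#' @return `mu + sigma * eps`.
#' @export
reparameterize <- function(mu, sigma, eps) {
  stopifnot(length(mu) == length(sigma), length(mu) == length(eps))
  mu + sigma * eps
}

#' ELBO components (minimization convention)
#'
#' Reconstruction is the squared error summed over genes; KL is the
#' closed form against a standard-normal latent prior,
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.  Both are averaged
#' over the batch (rows).
#'
#' @param x,xhat observed and reconstructed expression (row = cell).
#' @param mu,sigma variational posterior parameters (row = cell),
#'   `sigma > 0`.
#' @return list with `reconstruction`, `kl`, `elbo`
#'   (`reconstruction + kl`).
#' @export
elbo_terms <- function(x, xhat, mu, sigma) {
  x <- rbind(x); xhat <- rbind(xhat); mu <- rbind(mu); sigma <- rbind(sigma)
  if (!all(dim(x) == dim(xhat))) stop("x and xhat shapes differ")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  n <- nrow(x)
  recon <- sum((x - xhat)^2) / n
  kl <- 0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma)) / n
  list(reconstruction = recon, kl = kl, elbo = recon + kl)
}

#' Map TF activities to reconstructed expression
#'
#' The decoder's final, fully interpretable step: a bias-free linear map
#' through the GRN weight matrix, `xhat = e %*% W`.
#'
#' @param e activities, vector of length `n_TF` or matrix cells x TF.
#' @param W TF-by-gene weight matrix.
#' @return reconstructed expression (cells x genes, or a vector).
#' @export
reconstruct_expression <- function(e, W) {
  vec <- is.null(dim(e))
  e <- rbind(e)
  if (ncol(e) != nrow(W))
    stop(sprintf("activity length %d does not match %d TFs in W",
                 ncol(e), nrow(W)))
  out <- e %*% W
  if (vec) drop(out) else out
}
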