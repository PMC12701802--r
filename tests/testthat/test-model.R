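# Unit tests for the VAE components and the training loop, on small
# simulated datasets.

small_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- simulate_grn_dataset(simulation_config(
        n_cells = 200, n_genes = 80, n_tfs = 8, edges_per_tf = 12,
        seed = 5))
      fit <- grnvae(sim, control = grnvae_control(epochs = 40, seed = 5))
      memo <<- list(sim = sim, fit = fit)
    }
    memo
  }
})

test_that("the encoder produces strictly positive sigma, deterministically", {
  fit <- small_fit()$fit
  x <- fit$data$expression$values[3, ]
  e1 <- encode(fit, x)
  e2 <- encode(fit, x)
  expect_true(all(e1$sigma > 0))
  expect_identical(e1, e2)
  e0 <- encode(fit, rep(0, length(x)))
  expect_true(all(is.finite(e0$mu)) && all(is.finite(e0$sigma)))
  expect_error(encode(fit, c(NA, x[-1])), "non-finite")
})

test_that("the decoder TF head is non-negative and reproducible", {
  fit <- small_fit()$fit
  z <- seq(-2, 2, length.out = fit$control$latent_dim)
  e1 <- decode_tf(fit, z)
  expect_true(all(e1 >= 0))
  expect_identical(e1, decode_tf(fit, z))
  # pushed far negative, every ReLU unit shuts off
  expect_true(all(decode_tf(fit, rep(-1e6, length(z))) >=  0))
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  control <- grnvae_control(encoder_layers = 7, decoder_layers = 6,
                            latent_dim = 4, epochs = 1, seed = 1)
  n_genes <- 11; n_tfs <- 3; B <- 5
  p <- grnvae:::nn_init(n_genes, n_tfs, control)
  p[["grn"]] <- matrix(rnorm(n_tfs * n_genes), n_tfs, n_genes)
  X <- matrix(abs(rnorm(B * n_genes)), B, n_genes)
  e_ulm <- matrix(abs(rnorm(B * n_tfs)), B, n_tfs)
  eps <- matrix(rnorm(B * control$latent_dim), B, control$latent_dim)
  alpha <- 0.6; gamma <- 1e-2
  loss_at <- function(p) {
    cache <- grnvae:::nn_forward(p, control, X, e_ulm, alpha, eps)
    grnvae:::nn_loss(cache, X, p, gamma)$total
  }
  cache <- grnvae:::nn_forward(p, control, X, e_ulm, alpha, eps)
  g <- grnvae:::nn_backward(p, control, cache, X, gamma, alpha)
  h <- 1e-6
  for (nm in names(g)) {
    idx <- sample(length(p[[nm]]), min(4, length(p[[nm]])))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training reduces validation loss and replays its schedules", {
  res <- small_fit()
  h <- res$fit$history
  expect_lt(tail(h$val_total, 1), h$val_total[1])
  ctrl <- res$fit$control
  expect_equal(h$alpha,
               pmin(ctrl$alpha_max,
                    ctrl$alpha_start + (seq_len(nrow(h)) - 1) * ctrl$delta_alpha))
  expect_equal(h$gamma, ctrl$gamma_max * h$epoch / ctrl$epochs)
  expect_equal(h$m, mask_factor(h$epoch, ctrl$epochs))
  # loss accounting at every epoch
  expect_equal(h$total, h$reconstruction + h$kl + h$grn_l1, tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  sim <- simulate_grn_dataset(simulation_config(
    n_cells = 120, n_genes = 60, n_tfs = 6, edges_per_tf = 10, seed = 9))
  f1 <- grnvae(sim, control = grnvae_control(epochs = 15, seed = 3))
  f2 <- grnvae(sim, control = grnvae_control(epochs = 15, seed = 3))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$activities, f2$activities)
})

test_that("with alpha pinned at zero activities reduce to clipped ULM", {
  sim <- simulate_grn_dataset(simulation_config(
    n_cells = 100, n_genes = 60, n_tfs = 6, edges_per_tf = 10, seed = 4))
  fit <- grnvae(sim, control = grnvae_control(epochs = 3, seed = 4,
                                              alpha_start = 0, alpha_max = 0,
                                              delta_alpha = 0))
  expect_equal(unname(fit$activities), unname(pmax(fit$ulm, 0)))
})

test_that("inferred activities are non-negative, stable, and cluster-aware", {
  res <- small_fit()
  acts <- infer_activities(res$fit, res$sim$expression)
  expect_true(all(acts >= 0))
  expect_identical(acts, infer_activities(res$fit, res$sim$expression))
  # a TF that is on only in its own cluster scores higher there
  labs <- res$sim$labels[rownames(acts)]
  tf_cluster <- rep_len(seq_len(res$sim$config$n_clusters),
                        res$sim$config$n_tfs)
  for (k in seq_len(ncol(acts))) {
    own <- labs == paste0("C", tf_cluster[k])
    expect_gt(mean(acts[own, k]), mean(acts[!own, k]))
  }
})

test_that("prediction and residual methods are mutually consistent", {
  res <- small_fit()
  fit <- res$fit
  expect_equal(predict(fit), fit$activities)
  rec <- predict(fit, type = "expression")
  expect_equal(rec, fit$activities %*% fit$coefficients, ignore_attr = TRUE)
  expect_equal(residuals(fit), fit$data$expression$values - fitted(fit))
  expect_equal(coef(fit), fit$coefficients)
  s <- summary(fit)
  expect_s3_class(s, "summary.grnvae")
  expect_equal(s$n_tfs, nrow(coef(fit)))
})
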