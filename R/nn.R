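# Internal neural-network machinery: a small fully connected VAE with
# manual forward/backward passes and an Adam optimizer, written in base
# R matrix algebra.  The parameter set is a flat named list of matrices
# so the optimizer is generic over architecture.
#
# Layout:
#   enc<i>.W / enc<i>.b   encoder trunk (ReLU)
#   mu.W / mu.b           latent mean head
#   lv.W / lv.b           latent log-variance head (sigma = exp(lv/2))
#   dec<i>.W / dec<i>.b   decoder trunk (ReLU)
#   tf.W / tf.b           TF head (ReLU output => non-negative activity)
#   grn                   the explicit TF x gene weight matrix W

LV_CLAMP <- 12  # |log-variance| bound for numerical stability

dense_init <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

nn_init <- function(n_genes, n_tfs, control) {
  p <- list()
  sizes <- c(n_genes, control$encoder_layers)
  for (i in seq_along(control$encoder_layers)) {
    d <- dense_init(sizes[i], sizes[i + 1])
    p[[paste0("enc", i, ".W")]] <- d$W
    p[[paste0("enc", i, ".b")]] <- d$b
  }
  h <- tail(sizes, 1)
  d <- dense_init(h, control$latent_dim)
  p[["mu.W"]] <- d$W; p[["mu.b"]] <- d$b
  d <- dense_init(h, control$latent_dim)
  p[["lv.W"]] <- d$W; p[["lv.b"]] <- d$b
  sizes <- c(control$latent_dim, control$decoder_layers)
  for (i in seq_along(control$decoder_layers)) {
    d <- dense_init(sizes[i], sizes[i + 1])
    p[[paste0("dec", i, ".W")]] <- d$W
    p[[paste0("dec", i, ".b")]] <- d$b
  }
  d <- dense_init(tail(sizes, 1), n_tfs)
  p[["tf.W"]] <- d$W; p[["tf.b"]] <- d$b
  p[["grn"]] <- matrix(0, n_tfs, n_genes)  # caller overwrites with prior
  p
}

addb <- function(M, b) sweep(M, 2, b, "+")

# Full forward pass.  `eps = NULL` means eval mode (z = mu, no
# sampling).  Returns every intermediate needed by nn_backward.
nn_forward <- function(p, control, X, e_ulm, alpha, eps = NULL) {
  ne <- length(control$encoder_layers)
  nd <- length(control$decoder_layers)
  enc_in <- vector("list", ne); enc_pre <- vector("list", ne)
  H <- X
  for (i in seq_len(ne)) {
    enc_in[[i]] <- H
    Z <- addb(H %*% p[[paste0("enc", i, ".W")]], p[[paste0("enc", i, ".b")]])
    enc_pre[[i]] <- Z
    H <- relu(Z)
  }
  mu <- addb(H %*% p[["mu.W"]], p[["mu.b"]])
  lv_raw <- addb(H %*% p[["lv.W"]], p[["lv.b"]])
  lv <- pmin(pmax(lv_raw, -LV_CLAMP), LV_CLAMP)
  sigma <- exp(0.5 * lv)
  z <- if (is.null(eps)) mu else mu + sigma * eps
  dec_in <- vector("list", nd); dec_pre <- vector("list", nd)
  D <- z
  for (i in seq_len(nd)) {
    dec_in[[i]] <- D
    Z <- addb(D %*% p[[paste0("dec", i, ".W")]], p[[paste0("dec", i, ".b")]])
    dec_pre[[i]] <- Z
    D <- relu(Z)
  }
  tf_pre <- addb(D %*% p[["tf.W"]], p[["tf.b"]])
  e_dec <- relu(tf_pre)
  e_hat <- (1 - alpha) * e_ulm + alpha * e_dec
  xhat <- e_hat %*% p[["grn"]]
  list(H = H, mu = mu, lv_raw = lv_raw, lv = lv, sigma = sigma, z = z,
       eps = eps, enc_in = enc_in, enc_pre = enc_pre,
       dec_in = dec_in, dec_pre = dec_pre, D = D,
       tf_pre = tf_pre, e_dec = e_dec, e_hat = e_hat, xhat = xhat)
}

nn_loss <- function(cache, X, p, gamma) {
  n <- nrow(X)
  recon <- sum((X - cache$xhat)^2) / n
  kl <- 0.5 * sum(cache$mu^2 + cache$sigma^2 - 1 - cache$lv) / n
  l1 <- gamma * sum(abs(p[["grn"]]))
  list(reconstruction = recon, kl = kl, grn_l1 = l1,
       elbo = recon + kl, total = recon + kl + l1)
}

nn_backward <- function(p, control, cache, X, gamma, alpha) {
  g <- list()
  n <- nrow(X)
  ne <- length(control$encoder_layers)
  nd <- length(control$decoder_layers)

  G_xhat <- 2 * (cache$xhat - X) / n
  g[["grn"]] <- crossprod(cache$e_hat, G_xhat) + gamma * sign(p[["grn"]])
  G_ehat <- tcrossprod(G_xhat, p[["grn"]])
  G_tfpre <- alpha * G_ehat * (cache$tf_pre > 0)
  g[["tf.W"]] <- crossprod(cache$D, G_tfpre)
  g[["tf.b"]] <- colSums(G_tfpre)
  G <- tcrossprod(G_tfpre, p[["tf.W"]])
  for (i in rev(seq_len(nd))) {
    G <- G * (cache$dec_pre[[i]] > 0)
    g[[paste0("dec", i, ".W")]] <- crossprod(cache$dec_in[[i]], G)
    g[[paste0("dec", i, ".b")]] <- colSums(G)
    G <- tcrossprod(G, p[[paste0("dec", i, ".W")]])
  }
  G_z <- G
  G_mu <- G_z + cache$mu / n
  lv_open <- abs(cache$lv_raw) < LV_CLAMP
  G_lv <- (0.5 * G_z * (cache$eps %||% 0) * cache$sigma +
             (cache$sigma^2 - 1) / (2 * n)) * lv_open
  g[["mu.W"]] <- crossprod(cache$H, G_mu)
  g[["mu.b"]] <- colSums(G_mu)
  g[["lv.W"]] <- crossprod(cache$H, G_lv)
  g[["lv.b"]] <- colSums(G_lv)
  G <- tcrossprod(G_mu, p[["mu.W"]]) + tcrossprod(G_lv, p[["lv.W"]])
  for (i in rev(seq_len(ne))) {
    G <- G * (cache$enc_pre[[i]] > 0)
    g[[paste0("enc", i, ".W")]] <- crossprod(cache$enc_in[[i]], G)
    g[[paste0("enc", i, ".b")]] <- colSums(G)
    if (i > 1) G <- tcrossprod(G, p[[paste0("enc", i, ".W")]])
  }
  g
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0),
       v = lapply(p, function(x) x * 0),
       t = 0L)
}

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = p, state = state)
}

# Core epoch loop shared by grnvae() and finetune_clusters().  Schedules
# are supplied as closures over the epoch index so fine-tuning can pin
# them to constants.  RNG for shuffling and latent draws flows from the
# stream active when this is called (the callers wrap it in with_seed).
train_core <- function(p, control, X, e_ulm_clip, train_index, val_index,
                       W_prior, epochs, lr,
                       alpha, delta_alpha, alpha_max,
                       gamma_fn, mask_fn, verbose = FALSE) {
  state <- adam_init(p)
  bs <- control$batch_size
  best_val <- Inf; wait <- 0L
  hist <- vector("list", epochs)
  for (t in seq_len(epochs)) {
    gamma <- gamma_fn(t)
    ord <- sample(train_index)
    nb <- ceiling(length(ord) / bs)
    acc <- c(reconstruction = 0, kl = 0, grn_l1 = 0, total = 0)
    wtot <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * bs + 1):min(b * bs, length(ord))]
      Xb <- X[idx, , drop = FALSE]
      eps <- matrix(rnorm(length(idx) * control$latent_dim),
                    length(idx), control$latent_dim)
      cache <- nn_forward(p, control, Xb, e_ulm_clip[idx, , drop = FALSE],
                          alpha, eps)
      loss <- nn_loss(cache, Xb, p, gamma)
      if (!is.finite(loss$total))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", t))
      g <- nn_backward(p, control, cache, Xb, gamma, alpha)
      upd <- adam_step(p, g, state, lr)
      p <- upd$params; state <- upd$state
      w <- length(idx)
      acc <- acc + w * c(loss$reconstruction, loss$kl, loss$grn_l1, loss$total)
      wtot <- wtot + w
    }
    acc <- acc / wtot
    # epoch-level GRN blending toward the prior, then alpha advance
    m <- mask_fn(t)
    p[["grn"]] <- blend_grn(p[["grn"]], W_prior, m)
    alpha_used <- alpha
    alpha <- alpha_step(alpha, delta_alpha, alpha_max)
    # validation in eval mode (z = mu)
    Xv <- X[val_index, , drop = FALSE]
    vc <- nn_forward(p, control, Xv, e_ulm_clip[val_index, , drop = FALSE],
                     alpha_used, eps = NULL)
    vl <- nn_loss(vc, Xv, p, gamma)
    if (!is.finite(vl$total))
      stop(sprintf("training diverged at epoch %d (non-finite validation loss)", t))
    # plateau LR scheduler on validation total loss
    if (vl$total < best_val - 1e-10) {
      best_val <- vl$total; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$lr_patience) {
        lr <- lr * control$lr_factor
        wait <- 0L
      }
    }
    hist[[t]] <- data.frame(epoch = t,
                            reconstruction = acc[["reconstruction"]],
                            kl = acc[["kl"]],
                            grn_l1 = acc[["grn_l1"]],
                            total = acc[["total"]],
                            val_total = vl$total,
                            alpha = alpha_used, gamma = gamma, m = m, lr = lr)
    if (verbose && (t %% 10 == 0 || t == 1))
      message(sprintf("epoch %3d  train %.4f  val %.4f  alpha %.2f  m %.4f",
                      t, acc[["total"]], vl$total, alpha_used, m))
  }
  list(params = p, history = do.call(rbind, hist), alpha = alpha, lr = lr)
}
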