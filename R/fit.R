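#' Control parameters for [grnvae()]
#'
#' Collects the architecture and training hyperparameters with their
#' defaults.  The encoder has 1-3 hidden layers and the decoder 1-2
#' hidden layers before the TF head; the final GRN layer is always
#' present and is not counted here.
#'
#' @param encoder_layers integer vector of 1-3 encoder hidden sizes.
#' @param decoder_layers integer vector of 1-2 decoder hidden sizes.
#' @param latent_dim latent dimension.
#' @param alpha_start,alpha_max,delta_alpha activity-blending schedule:
#'   start value, ceiling, and per-epoch increment (all in `[0, 1]`,
#'   `alpha_start <= alpha_max`).
#' @param gamma_max terminal L1 coefficient of the linear ramp.
#' @param epochs total training epochs `T`.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param lr_factor,lr_patience plateau scheduler: multiply the learning
#'   rate by `lr_factor` after `lr_patience` epochs without improvement
#'   in validation total loss.
#' @param seed single integer governing the split, initialization,
#'   shuffling and latent draws.
#' @param finetune_lr_scale learning-rate multiplier for per-cluster
#'   fine-tuning.
#' @param finetune_epochs default epochs for fine-tuning.
#' @param mask_increasing use the rising mask variant (see
#'   [mask_factor()]).
#' @return A list of class `grnvae_control`.
#' @export
grnvae_control <- function(encoder_layers = 128,
                           decoder_layers = 64,
                           latent_dim = 32,
                           alpha_start = 0, alpha_max = 0.9,
                           delta_alpha = 0.02,
                           gamma_max = 1e-3,
                           epochs = 150,
                           batch_size = 128,
                           learning_rate = 1e-3,
                           lr_factor = 0.5, lr_patience = 10,
                           seed = 42,
                           finetune_lr_scale = 0.1,
                           finetune_epochs = 200,
                           mask_increasing = FALSE) {
  encoder_layers <- as.integer(encoder_layers)
  decoder_layers <- as.integer(decoder_layers)
  if (!(length(encoder_layers) %in% 1:3))
    stop("encoder_layers must list 1-3 hidden sizes")
  if (!(length(decoder_layers) %in% 1:2))
    stop("decoder_layers must list 1-2 hidden sizes")
  if (!(alpha_start >= 0 && alpha_start <= alpha_max && alpha_max <= 1))
    stop("need 0 <= alpha_start <= alpha_max <= 1")
  if (delta_alpha < 0 || gamma_max < 0)
    stop("delta_alpha and gamma_max must be non-negative")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(encoder_layers = encoder_layers,
                 decoder_layers = decoder_layers,
                 latent_dim = as.integer(latent_dim),
                 alpha_start = alpha_start, alpha_max = alpha_max,
                 delta_alpha = delta_alpha, gamma_max = gamma_max,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 seed = as.integer(seed),
                 finetune_lr_scale = finetune_lr_scale,
                 finetune_epochs = as.integer(finetune_epochs),
                 mask_increasing = isTRUE(mask_increasing)),
            class = "grnvae_control")
}

#' Fit the prior-guided GRN variational autoencoder
#'
#' Jointly infers per-cell non-negative TF activities and a weighted
#' TF-by-gene regulatory network from single-cell expression.  The
#' expression and prior are first jointly filtered and aligned (see
#' [filter_and_align()]), cells are split into training and validation
#' sets, ULM activity estimates are precomputed, and the VAE is trained
#' by Adam on minibatches.  Three schedules govern training: per-cell
#' activities are a convex blend `(1 - alpha) * ULM + alpha * decoder`
#' with `alpha` rising per epoch; after every epoch the GRN weights are
#' blended with the prior, `W <- m(t) * W_prior + (1 - m(t)) * W`, with
#' the mask `m(t)` decaying from 1 to 0; and the L1 penalty coefficient
#' ramps linearly to `gamma_max`.  `W` is initialized to the signed
#' prior.
#'
#' @param x expression input: an `expression_matrix`, a plain
#'   cells-by-genes matrix with dimnames, or a simulated dataset from
#'   [simulate_grn_dataset()] (whose bundled prior is used when `prior`
#'   is missing).
#' @param prior the prior GRN: a `prior_grn`, a TF-by-gene matrix, or a
#'   data frame edge list with columns (source, target, weight).
#' @param min_cells_per_gene,min_genes_per_cell,min_targets_per_tf
#'   joint filters; see [filter_and_align()].
#' @param val_fraction held-out fraction for validation (default 0.15).
#' @param control a [grnvae_control()] list.
#' @param verbose print per-epoch progress.
#' @return An object of class `grnvae` with components
#'   \item{coefficients}{the learned TF-by-gene weight matrix `W`;}
#'   \item{W_prior}{the frozen signed prior;}
#'   \item{activities}{cells-by-TF inferred activities (eval mode);}
#'   \item{ulm}{raw (unclipped) ULM t-statistics;}
#'   \item{history}{per-epoch loss components and schedule values;}
#'   \item{alpha, m_final, gamma_final}{terminal schedule values;}
#'   \item{data}{the aligned expression, indices and identifiers.}
#' @seealso [predict.grnvae()], [finetune_clusters()], [scale_grn()]
#' @export
grnvae <- function(x, prior = NULL,
                   min_cells_per_gene = 10, min_genes_per_cell = 3,
                   min_targets_per_tf = 10,
                   val_fraction = 0.15,
                   control = grnvae_control(),
                   verbose = FALSE) {
  cl <- match.call()
  if (inherits(x, "grn_sim")) {
    prior <- prior %||% x$prior
    x <- x$expression
  }
  if (is.null(prior)) stop("a prior GRN is required")
  if (is.data.frame(prior)) prior <- prior_edges_to_grn(prior)
  data <- filter_and_align(x, prior,
                           min_cells_per_gene = min_cells_per_gene,
                           min_genes_per_cell = min_genes_per_cell,
                           min_targets_per_tf = min_targets_per_tf)
  data <- split_train_val(data, val_fraction = val_fraction,
                          seed = derive_seed(control$seed, 1))
  X <- data$expression$values
  ulm_raw <- ulm_activities(data$expression, data$prior, nonnegative = FALSE)
  ulm_clip <- relu(ulm_raw)
  W_prior <- as.matrix(data$prior$weights)

  p <- with_seed(derive_seed(control$seed, 3),
                 nn_init(ncol(X), nrow(W_prior), control))
  p[["grn"]] <- W_prior

  gamma_fn <- function(t) gamma_schedule(t, control$epochs, control$gamma_max)
  mask_fn <- function(t) mask_factor(t, control$epochs,
                                     increasing = control$mask_increasing)
  fit <- with_seed(derive_seed(control$seed, 7),
                   train_core(p, control, X, ulm_clip,
                              data$train_index, data$val_index,
                              W_prior, control$epochs,
                              control$learning_rate,
                              control$alpha_start, control$delta_alpha,
                              control$alpha_max,
                              gamma_fn, mask_fn, verbose = verbose))

  obj <- structure(list(coefficients = named_grn(fit$params[["grn"]], data),
                        W_prior = named_grn(W_prior, data),
                        params = fit$params,
                        control = control,
                        alpha = fit$alpha,
                        m_final = mask_fn(control$epochs),
                        gamma_final = gamma_fn(control$epochs),
                        lr_final = fit$lr,
                        history = fit$history,
                        ulm = ulm_raw,
                        data = data,
                        call = cl),
                   class = "grnvae")
  obj$activities <- infer_activities(obj, data$expression)
  obj
}

named_grn <- function(W, data) {
  dimnames(W) <- list(data$prior$tf_ids, data$expression$gene_ids)
  W
}

prior_edges_to_grn <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  names(df)[1:2] <- c("source", "target")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_prior_edges(tmp)
}

#' Encode expression into the variational posterior
#'
#' @param model a fitted `grnvae` object.
#' @param x a gene-expression vector (length `n_genes`, model gene
#'   order) or a cells-by-genes matrix.
#' @return list with `mu` and `sigma` (strictly positive), each
#'   cells x latent.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "grnvae"))
  x <- rbind(x)
  if (ncol(x) != length(model$data$expression$gene_ids))
    stop("input length does not match the model's gene set")
  stopifnot_finite(x, "expression input")
  cache <- nn_forward(model$params, model$control, x,
                      matrix(0, nrow(x), length(model$data$prior$tf_ids)),
                      alpha = 1, eps = NULL)
  list(mu = cache$mu, sigma = cache$sigma)
}

#' Decode a latent vector into decoder TF activities
#'
#' Runs the decoder trunk and ReLU TF head only (no ULM blending, no
#' gene reconstruction).
#'
#' @param model a fitted `grnvae` object.
#' @param z latent vector (length `latent_dim`) or matrix.
#' @return non-negative activities, cells x TF.
#' @export
decode_tf <- function(model, z) {
  stopifnot(inherits(model, "grnvae"))
  z <- rbind(z)
  if (ncol(z) != model$control$latent_dim)
    stop("latent dimension mismatch")
  p <- model$params
  D <- z
  for (i in seq_along(model$control$decoder_layers))
    D <- relu(addb(D %*% p[[paste0("dec", i, ".W")]],
                   p[[paste0("dec", i, ".b")]]))
  e <- relu(addb(D %*% p[["tf.W"]], p[["tf.b"]]))
  colnames(e) <- model$data$prior$tf_ids
  e
}

#' Infer per-cell TF activities with a fitted model
#'
#' Eval-mode forward pass: the latent is the posterior mean (`z = mu`,
#' no sampling), decoder activities are blended with ReLU-clipped ULM
#' estimates at the model's terminal `alpha`.  All outputs are
#' non-negative.
#'
#' @param model a fitted `grnvae` object.
#' @param expr an `expression_matrix` or matrix whose genes include the
#'   model's gene set (columns are matched by name and reordered).
#' @return cells x TF activity matrix.
#' @export
infer_activities <- function(model, expr) {
  stopifnot(inherits(model, "grnvae"))
  expr <- as_expression_matrix(expr)
  genes <- model$data$expression$gene_ids
  missing <- setdiff(genes, expr$gene_ids)
  if (length(missing))
    stop(sprintf("expression lacks %d genes required by the model (e.g. %s)",
                 length(missing), missing[1]))
  X <- expr$values[, genes, drop = FALSE]
  em <- expression_matrix(X, is_lognorm = expr$is_lognorm)
  ulm_clip <- ulm_activities(em, model$data$prior, nonnegative = TRUE)
  cache <- nn_forward(model$params, model$control, X, ulm_clip,
                      alpha = model$alpha, eps = NULL)
  acts <- cache$e_hat
  dimnames(acts) <- list(rownames(X), model$data$prior$tf_ids)
  acts
}
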