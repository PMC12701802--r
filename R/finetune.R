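#' Per-cluster fine-tuning of a fitted model
#'
#' Refines the global fit into cell-type-specific models: for every
#' cluster with at least `min_cluster_size` cells, training continues
#' from a copy of the global parameters on that cluster's cells only, at
#' `learning_rate * finetune_lr_scale`.  The schedules are pinned to
#' their terminal global values so fine-tuning is purely data-driven:
#' `alpha` stays at `alpha_max`, the mask is held constant at `m(T)`
#' (essentially zero, so the prior no longer constrains `W`), and the L1
#' coefficient stays at `gamma_max`.  Clusters below the minimum size
#' are skipped with a warning.
#'
#' @param model a fitted `grnvae` object.
#' @param labels cluster/cell-type labels: a vector named by cell id, or
#'   in the order of the model's cells.  Every model cell must be
#'   labeled.
#' @param epochs fine-tuning epochs per cluster (default
#'   `control$finetune_epochs`).  `epochs = 0` returns per-cluster
#'   copies of the global model unchanged.
#' @param min_cluster_size minimum cells per cluster (default 20).
#' @param val_fraction validation fraction inside each cluster.
#' @param verbose print progress.
#' @return A named list, one element per fine-tuned cluster, each with
#'   `model` (a `grnvae` object restricted to the cluster's cells), `W`
#'   (the cluster GRN) and `activities` (cluster cells x TF).
#' @export
finetune_clusters <- function(model, labels, epochs = NULL,
                              min_cluster_size = 20, val_fraction = 0.15,
                              verbose = FALSE) {
  stopifnot(inherits(model, "grnvae"))
  cells <- model$data$expression$cell_ids
  if (!is.null(names(labels))) {
    if (!all(cells %in% names(labels)))
      stop("every model cell must be labeled")
    labels <- labels[cells]
  } else if (length(labels) != length(cells)) {
    stop("labels must cover all model cells")
  }
  labels <- as.character(labels)
  control <- model$control
  epochs <- epochs %||% control$finetune_epochs
  lr <- control$learning_rate * control$finetune_lr_scale
  W_prior <- model$W_prior
  m_final <- model$m_final
  gamma_final <- model$gamma_final
  X <- model$data$expression$values
  ulm_clip <- relu(model$ulm)

  out <- list()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < min_cluster_size) {
      warning(sprintf("cluster '%s' has %d cells (< %d); skipped",
                      cl, length(idx), min_cluster_size))
      next
    }
    sub <- model
    sub$data$expression <- expression_matrix(
      X[idx, , drop = FALSE], is_lognorm = model$data$expression$is_lognorm)
    sub$ulm <- model$ulm[idx, , drop = FALSE]
    if (epochs > 0) {
      n <- length(idx)
      n_val <- min(max(round(val_fraction * n), 1L), n - 1L)
      seed_cl <- derive_seed(control$seed, 1000L + match(cl, sort(unique(labels))))
      perm <- with_seed(seed_cl, sample.int(n))
      val_i <- sort(perm[seq_len(n_val)]); train_i <- sort(perm[-seq_len(n_val)])
      fit <- with_seed(derive_seed(seed_cl, 7),
                       train_core(model$params, control,
                                  X[idx, , drop = FALSE],
                                  ulm_clip[idx, , drop = FALSE],
                                  train_i, val_i, W_prior,
                                  epochs, lr,
                                  alpha = model$alpha, delta_alpha = 0,
                                  alpha_max = max(model$alpha, control$alpha_max),
                                  gamma_fn = function(t) gamma_final,
                                  mask_fn = function(t) m_final,
                                  verbose = verbose))
      sub$params <- fit$params
      sub$coefficients <- named_grn(fit$params[["grn"]], model$data)
      sub$history <- rbind(model$history, fit$history)
      sub$data$train_index <- train_i
      sub$data$val_index <- val_i
    }
    sub$activities <- infer_activities(sub, sub$data$expression)
    out[[cl]] <- list(model = sub, W = sub$coefficients,
                      activities = sub$activities)
  }
  if (!length(out)) stop("no cluster reached the minimum size")
  out
}
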