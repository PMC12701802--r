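# S3 methods for fitted grnvae objects.

#' @exportS3Method base::print
print.grnvae <- function(x, ...) {
  d <- x$data
  cat("Prior-guided GRN variational autoencoder\n")
  cat(sprintf("  %d cells x %d genes, %d TFs\n",
              length(d$expression$cell_ids), length(d$expression$gene_ids),
              length(d$prior$tf_ids)))
  cat(sprintf("  epochs: %d   final train loss: %.4f   val loss: %.4f\n",
              nrow(x$history), tail(x$history$total, 1),
              tail(x$history$val_total, 1)))
  cat(sprintf("  alpha: %.3f   mask m(T): %.2e   gamma(T): %.2e\n",
              x$alpha, x$m_final, x$gamma_final))
  invisible(x)
}

#' Summarize a fitted grnvae model
#'
#' @param object a `grnvae` fit.
#' @param n_top number of TFs to report by mean inferred activity.
#' @param ... unused.
#' @return A `summary.grnvae` list with dimensions, loss trajectory
#'   endpoints, GRN sparsity and the most active TFs.
#' @exportS3Method base::summary
#' @export summary.grnvae
summary.grnvae <- function(object, n_top = 10, ...) {
  W <- object$coefficients
  mean_act <- colMeans(object$activities)
  top <- sort(mean_act, decreasing = TRUE)[seq_len(min(n_top, length(mean_act)))]
  out <- list(n_cells = nrow(object$activities),
              n_genes = ncol(W), n_tfs = nrow(W),
              epochs = nrow(object$history),
              loss_first = object$history$total[1],
              loss_last = tail(object$history$total, 1),
              val_last = tail(object$history$val_total, 1),
              prior_edges = sum(object$W_prior != 0),
              w_nonzero = sum(abs(W) > 1e-6),
              top_tfs = top)
  class(out) <- "summary.grnvae"
  out
}

#' @exportS3Method base::print
print.summary.grnvae <- function(x, ...) {
  cat(sprintf("grnvae fit: %d cells, %d genes, %d TFs, %d epochs\n",
              x$n_cells, x$n_genes, x$n_tfs, x$epochs))
  cat(sprintf("  training loss %.4f -> %.4f (validation %.4f)\n",
              x$loss_first, x$loss_last, x$val_last))
  cat(sprintf("  prior edges: %d; |W| > 1e-6: %d\n",
              x$prior_edges, x$w_nonzero))
  cat("  top TFs by mean activity:\n")
  print(round(x$top_tfs, 3))
  invisible(x)
}

#' Extract the learned GRN weight matrix
#'
#' @param object a `grnvae` fit.
#' @param scaled if `TRUE`, return per-TF min-max scaled weights (see
#'   [scale_grn()]).
#' @param ... unused.
#' @return TF-by-gene numeric matrix.
#' @export
coef.grnvae <- function(object, scaled = FALSE, ...) {
  if (scaled) scale_grn(object$coefficients)$weights
  else object$coefficients
}

#' Predict TF activities or reconstructed expression
#'
#' @param object a `grnvae` fit.
#' @param newdata optional expression matrix; defaults to the training
#'   data.
#' @param type `"activities"` for cells x TF activities (eval-mode
#'   forward pass) or `"expression"` for the reconstruction
#'   `activities %*% W`.
#' @param ... unused.
#' @return numeric matrix.
#' @export
predict.grnvae <- function(object, newdata = NULL,
                           type = c("activities", "expression"), ...) {
  type <- match.arg(type)
  acts <- if (is.null(newdata)) object$activities
          else infer_activities(object, newdata)
  if (type == "activities") acts
  else reconstruct_expression(acts, object$coefficients)
}

#' @export
fitted.grnvae <- function(object, ...) {
  reconstruct_expression(object$activities, object$coefficients)
}

#' @export
residuals.grnvae <- function(object, ...) {
  object$data$expression$values - fitted(object)
}

#' Plot training and validation loss trajectories
#'
#' @param x a `grnvae` fit.
#' @param ... passed to `plot`.
#' @export
plot.grnvae <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$total, h$val_total))
  plot(h$epoch, h$total, type = "l", xlab = "epoch", ylab = "total loss",
       ylim = rng, ...)
  lines(h$epoch, h$val_total, lty = 2)
  legend("topright", legend = c("train", "validation"), lty = 1:2,
         bty = "n")
  invisible(x)
}
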