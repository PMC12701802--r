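# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately takes a different computational route than
# the package implementation it checks.

# Exhaustive threshold-sweep ROC/PR areas: loops over every distinct
# score as a binarization threshold and integrates the resulting curves
# (trapezoid for ROC, rectangular/average-precision for PR).
sweep_roc_pr <- function(scores, labels) {
  labels <- as.numeric(labels != 0)
  P <- sum(labels); N <- sum(labels == 0)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    tpr[i] <- tp / P; fpr[i] <- fp / N
    prec[i] <- tp / (tp + fp); rec[i] <- tp / P
  }
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc)
}

# Per-(cell, TF) slope t-statistics via stats::lm / summary.lm.
lm_ulm_oracle <- function(X, W) {
  out <- matrix(0, nrow(X), nrow(W))
  for (i in seq_len(nrow(X))) {
    for (k in seq_len(nrow(W))) {
      fit <- summary(lm(X[i, ] ~ W[k, ]))
      out[i, k] <- if (nrow(fit$coefficients) < 2) 0
                   else fit$coefficients[2, "t value"]
    }
  }
  out
}

# Tiny deterministic expression + prior pair used by several IO tests.
make_tiny_dataset <- function(n_cells = 50, n_genes = 30, n_tfs = 4,
                              targets_per_tf = 12, seed = 1) {
  targets_per_tf <- min(targets_per_tf, n_genes)
  with_seed_local(seed, {
    X <- matrix(rpois(n_cells * n_genes, 2), n_cells, n_genes,
                dimnames = list(sprintf("c%02d", 1:n_cells),
                                sprintf("g%02d", 1:n_genes)))
    P <- matrix(0, n_tfs, n_genes,
                dimnames = list(sprintf("tf%d", 1:n_tfs), colnames(X)))
    for (k in seq_len(n_tfs))
      P[k, sample(n_genes, targets_per_tf)] <- sample(c(-1, 1),
                                                      targets_per_tf,
                                                      replace = TRUE)
    list(X = X, P = P)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

write_edge_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
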