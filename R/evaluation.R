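# Benchmarking utilities: dropout simulation, activity-space Leiden
# clustering with majority-vote labels and agreement metrics, GRN
# edge-recovery AUROC/AUPRC, proportional stratified sketching, and
# knockdown evaluation.

#' Bernoulli dropout mask on an expression matrix
#'
#' Each entry is independently retained with probability `1 - p` and
#' set to zero otherwise, mimicking technical dropout.
#'
#' @param expr an `expression_matrix` or matrix.
#' @param p zeroing probability in `[0, 1)`.
#' @param seed integer seed (mask is deterministic given the seed).
#' @return An `expression_matrix` of the same shape.
#' @export
dropout_mask <- function(expr, p, seed = 1) {
  expr <- as_expression_matrix(expr)
  if (!(p >= 0 && p < 1)) stop("p must be in [0, 1)")
  if (p == 0) return(expr)
  X <- expr$values
  keep <- with_seed(seed, matrix(runif(length(X)) > p, nrow(X), ncol(X)))
  expression_matrix(X * keep, is_lognorm = expr$is_lognorm)
}

# Shared k-nearest-neighbour graph (Euclidean, undirected union of
# neighbourhoods).  Dense distances: intended for desk-scale inputs.
knn_graph <- function(X, k = 15) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 cells")
  k <- min(k, n - 1)
  d <- as.matrix(dist(X))
  nb <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden clustering of TF activities across resolutions
#'
#' Builds a k-nearest-neighbour graph on the activity matrix (Euclidean
#' on the raw activities) and partitions it with the Leiden algorithm at
#' each requested resolution.
#'
#' @param acts cells x TF activity matrix.
#' @param resolutions numeric vector of resolutions (default the sweep
#'   `seq(0.2, 3.0, by = 0.2)`).
#' @param k neighbours in the kNN graph (default 15).
#' @param seed integer seed; partitions are deterministic given the
#'   seed.
#' @return named list (one element per resolution, names are the
#'   resolution values) of integer membership vectors named by cell id.
#' @export
cluster_activities <- function(acts, resolutions = seq(0.2, 3.0, by = 0.2),
                               k = 15, seed = 1) {
  acts <- as.matrix(acts)
  if (any(resolutions <= 0)) stop("resolutions must be positive")
  g <- knn_graph(acts, k = k)
  out <- lapply(resolutions, function(r) {
    memb <- with_seed(derive_seed(seed, round(1000 * r)),
                      igraph::cluster_leiden(
                        g, objective_function = "modularity",
                        resolution = r, n_iterations = 5)$membership)
    names(memb) <- rownames(acts)
    memb
  })
  names(out) <- as.character(resolutions)
  out
}

#' Majority-vote labels for predicted clusters
#'
#' Assigns every cell the modal ground-truth label of its cluster; ties
#' are broken by lexicographic label order.
#'
#' @param pred_clusters cluster memberships (any label type).
#' @param true_labels ground-truth labels, same length/order.
#' @return character vector of assigned labels (named like
#'   `true_labels` when names are present).
#' @export
majority_vote_labels <- function(pred_clusters, true_labels) {
  stopifnot(length(pred_clusters) == length(true_labels))
  true_labels <- as.character(true_labels)
  out <- character(length(true_labels))
  for (cl in unique(pred_clusters)) {
    i <- pred_clusters == cl
    tab <- table(true_labels[i])
    winners <- names(tab)[tab == max(tab)]
    out[i] <- sort(winners)[1]
  }
  names(out) <- names(true_labels)
  out
}

# Mann-Whitney AUROC with midrank tie handling.
auroc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision over the distinct-threshold sweep (ties grouped).
auprc_score <- function(scores, labels) {
  labels <- as.numeric(as.logical(labels))
  P <- sum(labels)
  if (P == 0 || P == length(labels)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(which(diff(s) != 0), length(s))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Clustering agreement metrics
#'
#' Compares majority-vote assigned labels with ground truth: adjusted
#' Rand index (permutation model), normalized mutual information
#' (arithmetic normalization), macro F1 over the true label set, and a
#' macro one-vs-rest AUC that treats the assigned-label indicator as
#' the score for each class.
#'
#' @param assigned per-cell labels after majority voting.
#' @param truth ground-truth labels, same length.
#' @return list of class `clustering_report`: `ari`, `nmi`, `macro_f1`,
#'   `auc`, `n_clusters` (distinct assigned labels).
#' @export
clustering_metrics <- function(assigned, truth) {
  stopifnot(length(assigned) == length(truth))
  assigned <- as.character(assigned); truth <- as.character(truth)
  if (length(unique(truth)) < 2)
    stop("ARI/NMI are undefined for a single true class")
  a <- as.integer(factor(assigned))
  b <- as.integer(factor(truth))
  ari <- igraph::compare(a, b, method = "adjusted.rand")
  nmi <- igraph::compare(a, b, method = "nmi")
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(assigned == cl & truth == cl)
    fp <- sum(assigned == cl & truth != cl)
    fn <- sum(assigned != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  auc <- vapply(classes, function(cl)
    auroc_score(as.numeric(assigned == cl), truth == cl), numeric(1))
  structure(list(ari = ari, nmi = nmi, macro_f1 = mean(f1),
                 auc = mean(auc, na.rm = TRUE),
                 n_clusters = length(unique(assigned))),
            class = "clustering_report")
}

#' @exportS3Method base::print
print.clustering_report <- function(x, ...) {
  cat(sprintf("ARI %.3f  NMI %.3f  macro-F1 %.3f  AUC %.3f  (%d clusters)\n",
              x$ari, x$nmi, x$macro_f1, x$auc, x$n_clusters))
  invisible(x)
}

#' GRN edge-recovery AUROC and AUPRC
#'
#' Scores the absolute predicted weights against a binary ground-truth
#' network over the intersection of TF and gene sets (matched by
#' dimnames when present), sweeping all binarization thresholds.  Tied
#' scores are handled by midranks (AUROC) and grouped thresholds
#' (AUPRC).
#'
#' @param pred TF-by-gene real matrix of predicted weights.
#' @param truth binary TF-by-gene matrix (or a `grn_sim` truth entry).
#' @return list with `auroc`, `auprc`, `n` (entries scored) and
#'   `prevalence`.
#' @export
grn_auroc_auprc <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  named <- function(M) !is.null(rownames(M)) && !is.null(colnames(M))
  if (named(pred) && named(truth)) {
    tfs <- intersect(rownames(pred), rownames(truth))
    genes <- intersect(colnames(pred), colnames(truth))
    if (!length(tfs) || !length(genes))
      stop("no TF/gene overlap between prediction and truth")
    pred <- pred[tfs, genes, drop = FALSE]
    truth <- truth[tfs, genes, drop = FALSE]
  } else if (!all(dim(pred) == dim(truth))) {
    stop("unnamed matrices must share dimensions")
  }
  y <- as.numeric(truth != 0)
  if (all(y == 0) || all(y == 1))
    stop("ground truth is constant on the evaluated intersection")
  s <- abs(as.numeric(pred))
  list(auroc = auroc_score(s, y), auprc = auprc_score(s, y),
       n = length(y), prevalence = mean(y))
}

#' Proportional stratified sketching
#'
#' Splits cells into `n_subsets` disjoint subsets that preserve the
#' composition of pseudo-clusters: clusters are computed by Leiden on a
#' PCA reduction of the expression (unless supplied), then each
#' cluster's cells are dealt across subsets, so every subset receives a
#' share proportional to cluster size (within one cell).  The seeded
#' uniform within-cluster split is the default sketching backend; a
#' custom assignment can be plugged in via `clusters`.
#'
#' @param expr an `expression_matrix` or matrix.
#' @param n_subsets number of subsets (default 5).
#' @param seed integer seed.
#' @param clusters optional precomputed pseudo-cluster labels (vector,
#'   cell order); skips the Leiden step.
#' @param resolution Leiden resolution for pseudo-clusters (default 1).
#' @param k kNN neighbours (default 15).
#' @param n_pcs principal components retained (default 20).
#' @return list of `n_subsets` sorted integer index vectors; pairwise
#'   disjoint and jointly exhaustive.
#' @export
stratified_sketch <- function(expr, n_subsets = 5, seed = 1,
                              clusters = NULL, resolution = 1.0,
                              k = 15, n_pcs = 20) {
  expr <- as_expression_matrix(expr)
  n <- nrow(expr$values)
  if (n_subsets < 2) stop("n_subsets must be >= 2")
  if (n_subsets > n) stop("more subsets than cells")
  if (is.null(clusters)) {
    npc <- min(n_pcs, n - 1, ncol(expr$values))
    pcs <- prcomp(expr$values, rank. = npc, center = TRUE)$x
    clusters <- with_seed(derive_seed(seed, 21),
                          igraph::cluster_leiden(
                            knn_graph(pcs, k = k),
                            objective_function = "modularity",
                            resolution = resolution,
                            n_iterations = 5)$membership)
  }
  stopifnot(length(clusters) == n)
  subsets <- vector("list", n_subsets)
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    idx <- with_seed(derive_seed(seed, 22L + match(cl, unique(clusters))),
                     sample(idx))
    bins <- rep_len(seq_len(n_subsets), length(idx))
    for (s in seq_len(n_subsets))
      subsets[[s]] <- c(subsets[[s]], idx[bins == s])
  }
  lapply(subsets, sort)
}

#' Knockdown evaluation of inferred TF activity
#'
#' Compares a TF's inferred activity between control and knockdown
#' cells: effect size is
#' `log2((mean_kd + eps) / (mean_ctrl + eps))` and significance a
#' two-sided Wilcoxon rank-sum test.  CRISPRi-style repression should
#' yield a negative LFC.
#'
#' @param acts_ctrl,acts_kd cells x TF activity matrices for control
#'   and knockdown conditions.
#' @param perturbed_tf TF identifier present in both matrices.
#' @param eps pseudo-count (default 1e-9).
#' @return list with `lfc`, `p_value`, `mean_ctrl`, `mean_kd`,
#'   `n_ctrl`, `n_kd`.
#' @export
knockdown_evaluation <- function(acts_ctrl, acts_kd, perturbed_tf,
                                 eps = 1e-9) {
  acts_ctrl <- as.matrix(acts_ctrl); acts_kd <- as.matrix(acts_kd)
  if (!nrow(acts_ctrl) || !nrow(acts_kd))
    stop("both conditions must contain cells")
  if (!(perturbed_tf %in% colnames(acts_ctrl)) ||
      !(perturbed_tf %in% colnames(acts_kd)))
    stop("TF not present in both conditions: ", perturbed_tf)
  vc <- acts_ctrl[, perturbed_tf]; vk <- acts_kd[, perturbed_tf]
  lfc <- log2((mean(vk) + eps) / (mean(vc) + eps))
  p <- if (all(vk == vc[1]) && all(vc == vc[1])) 1
       else suppressWarnings(wilcox.test(vk, vc)$p.value)
  list(lfc = lfc, p_value = p, mean_ctrl = mean(vc), mean_kd = mean(vk),
       n_ctrl = length(vc), n_kd = length(vk))
}

#' Knockdown screen across TFs
#'
#' Applies [knockdown_evaluation()] to each TF shared by the two
#' matrices and adjusts p-values by Benjamini-Hochberg.
#'
#' @inheritParams knockdown_evaluation
#' @param tfs TFs to test (default: all shared TFs).
#' @return data.frame with `tf`, `lfc`, `p_value`, `p_adj`.
#' @export
knockdown_screen <- function(acts_ctrl, acts_kd, tfs = NULL, eps = 1e-9) {
  tfs <- tfs %||% intersect(colnames(acts_ctrl), colnames(acts_kd))
  rows <- lapply(tfs, function(tf) {
    r <- knockdown_evaluation(acts_ctrl, acts_kd, tf, eps = eps)
    data.frame(tf = tf, lfc = r$lfc, p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_value, "BH")
  out
}
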