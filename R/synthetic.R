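#' Configuration for the synthetic GRN benchmark generator
#'
#' Defines a controlled ground-truth regime: a signed TF-by-gene network
#' with log-normal edge magnitudes, cluster-structured non-negative TF
#' activities (Gamma-distributed, high mean where a TF is "on"),
#' expression generated as `activities %*% W_truth` plus Gaussian noise
#' clipped at zero, optional Bernoulli dropout, and an exported prior
#' that may be partially corrupted (a fraction of true edges replaced by
#' random false ones).
#'
#' @param n_cells,n_genes,n_tfs,n_clusters problem dimensions.
#' @param edges_per_tf targets per TF in the truth network.
#' @param sign_fraction_negative probability an edge is repressive.
#' @param activity_mean_on,activity_mean_off Gamma means of a TF's
#'   activity in cells of its assigned cluster(s) vs elsewhere.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param dropout_p Bernoulli zeroing probability in `[0, 1)`.
#' @param prior_corruption fraction of truth edges replaced by false
#'   edges in the exported prior, in `[0, 1]`.
#' @param cluster_rewire fraction of each TF's edges rewired per cluster
#'   to create cluster-specific truth networks (0 = one shared truth).
#' @param seed integer seed; the dataset is a pure function of the
#'   configuration.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 500, n_genes = 200, n_tfs = 15,
                              n_clusters = 3, edges_per_tf = 15,
                              sign_fraction_negative = 0.25,
                              activity_mean_on = 5,
                              activity_mean_off = 0.5,
                              noise_sd = 0.5, dropout_p = 0,
                              prior_corruption = 0,
                              cluster_rewire = 0,
                              seed = 42) {
  stopifnot(n_tfs <= n_genes, edges_per_tf >= 1, edges_per_tf <= n_genes,
            sign_fraction_negative >= 0, sign_fraction_negative <= 1,
            activity_mean_on > 0, activity_mean_off > 0, noise_sd >= 0,
            dropout_p >= 0, dropout_p < 1,
            prior_corruption >= 0, prior_corruption <= 1,
            cluster_rewire >= 0, cluster_rewire <= 1,
            n_clusters >= 1, n_cells >= n_clusters)
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_tfs = as.integer(n_tfs),
                 n_clusters = as.integer(n_clusters),
                 edges_per_tf = as.integer(edges_per_tf),
                 sign_fraction_negative = sign_fraction_negative,
                 activity_mean_on = activity_mean_on,
                 activity_mean_off = activity_mean_off,
                 noise_sd = noise_sd, dropout_p = dropout_p,
                 prior_corruption = prior_corruption,
                 cluster_rewire = cluster_rewire,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

ACT_SHAPE <- 4      # Gamma shape of simulated activities
EDGE_SDLOG <- 0.25  # log-normal sd of edge magnitudes

#' Simulate a single-cell dataset from a known GRN
#'
#' See [simulation_config()] for the generative model.  Cells are
#' balanced across clusters; TF `k` is assigned to cluster
#' `(k - 1) %% n_clusters + 1` and is "on" only there.  With
#' `cluster_rewire > 0` every cluster gets its own truth network
#' obtained by rewiring that fraction of each TF's targets.
#'
#' @param config a `simulation_config`.
#' @return An object of class `grn_sim`: list with `expression`
#'   (an `expression_matrix`), `truth_weights` (signed TF x gene matrix,
#'   or a per-cluster list when rewired), `truth_grn` (binary support,
#'   same structure), `truth_activities` (cells x TF), `labels` (named
#'   cluster factor), `prior` (a possibly corrupted `prior_grn`) and
#'   `config`.
#' @export
simulate_grn_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("cell%04d", seq_len(cfg$n_cells))

  # 1. signed truth network(s)
  base_W <- with_seed(derive_seed(cfg$seed, 11), {
    W <- matrix(0, cfg$n_tfs, cfg$n_genes,
                dimnames = list(tf_ids, gene_ids))
    for (k in seq_len(cfg$n_tfs)) {
      tg <- sample.int(cfg$n_genes, cfg$edges_per_tf)
      sg <- ifelse(runif(cfg$edges_per_tf) < cfg$sign_fraction_negative, -1, 1)
      W[k, tg] <- sg * rlnorm(cfg$edges_per_tf, 0, EDGE_SDLOG)
    }
    W
  })
  per_cluster <- cfg$cluster_rewire > 0 && cfg$n_clusters > 1
  if (per_cluster) {
    W_list <- with_seed(derive_seed(cfg$seed, 12), {
      lapply(seq_len(cfg$n_clusters), function(cl) {
        W <- base_W
        for (k in seq_len(cfg$n_tfs)) {
          cur <- which(W[k, ] != 0)
          nr <- round(cfg$cluster_rewire * length(cur))
          if (nr < 1) next
          drop_idx <- sample(cur, nr)
          free <- setdiff(seq_len(cfg$n_genes), setdiff(cur, drop_idx))
          add_idx <- sample(free, nr)
          W[k, drop_idx] <- 0
          sg <- ifelse(runif(nr) < cfg$sign_fraction_negative, -1, 1)
          W[k, add_idx] <- sg * rlnorm(nr, 0, EDGE_SDLOG)
        }
        W
      })
    })
    names(W_list) <- sprintf("C%d", seq_len(cfg$n_clusters))
  }

  # 2. cluster labels (balanced) and activities
  labels <- with_seed(derive_seed(cfg$seed, 13),
                      sample(rep_len(seq_len(cfg$n_clusters), cfg$n_cells)))
  names(labels) <- cell_ids
  tf_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_tfs)
  A <- with_seed(derive_seed(cfg$seed, 14), {
    on <- outer(labels, tf_cluster, "==")
    mu <- ifelse(on, cfg$activity_mean_on, cfg$activity_mean_off)
    matrix(rgamma(length(mu), shape = ACT_SHAPE, rate = ACT_SHAPE / mu),
           cfg$n_cells, cfg$n_tfs, dimnames = list(cell_ids, tf_ids))
  })

  E <- simulate_expression(A, labels,
                           if (per_cluster) W_list else base_W, cfg)

  # 5. exported prior (support of the base truth, possibly corrupted)
  prior <- with_seed(derive_seed(cfg$seed, 17), {
    S <- sign(base_W)
    n_edges <- sum(S != 0)
    n_cor <- round(cfg$prior_corruption * n_edges)
    if (n_cor > 0) {
      union_support <- if (per_cluster)
        Reduce(`|`, lapply(W_list, function(w) w != 0)) else (base_W != 0)
      edge_idx <- which(S != 0)
      free_idx <- which(!union_support & S == 0)
      drop_idx <- sample(edge_idx, n_cor)
      add_idx <- sample(free_idx, min(n_cor, length(free_idx)))
      S[drop_idx] <- 0
      S[add_idx] <- ifelse(runif(length(add_idx)) <
                             cfg$sign_fraction_negative, -1, 1)
    }
    prior_grn(S)
  })

  structure(list(expression = E,
                 truth_weights = if (per_cluster) W_list else base_W,
                 truth_grn = if (per_cluster)
                   lapply(W_list, function(w) (w != 0) * 1)
                 else (base_W != 0) * 1,
                 truth_activities = A,
                 labels = sprintf("C%d", labels) |> stats::setNames(cell_ids),
                 prior = prior,
                 config = cfg),
            class = "grn_sim")
}

# Expression = activities %*% W (per cluster when W is a list), plus
# Gaussian noise, clipped at zero, then Bernoulli dropout.  Noise and
# dropout draw from seed streams derived only from the config, so
# regenerating with modified activities reuses the identical noise.
simulate_expression <- function(A, labels, W, cfg) {
  if (is.list(W)) {
    M <- matrix(0, nrow(A), cfg$n_genes)
    for (cl in seq_along(W)) {
      idx <- which(labels == cl)
      M[idx, ] <- A[idx, , drop = FALSE] %*% W[[cl]]
    }
  } else {
    M <- A %*% W
  }
  noise <- with_seed(derive_seed(cfg$seed, 15),
                     matrix(rnorm(length(M), 0, cfg$noise_sd),
                            nrow(M), ncol(M)))
  X <- pmax(M + noise, 0)
  if (cfg$dropout_p > 0) {
    keep <- with_seed(derive_seed(cfg$seed, 16),
                      matrix(runif(length(X)) > cfg$dropout_p,
                             nrow(X), ncol(X)))
    X <- X * keep
  }
  dimnames(X) <- list(rownames(A),
                      sprintf("G%04d", seq_len(cfg$n_genes)))
  expression_matrix(X, is_lognorm = TRUE)
}

#' @exportS3Method base::print
print.grn_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("grn_sim: %d cells x %d genes, %d TFs, %d clusters\n",
              cfg$n_cells, cfg$n_genes, cfg$n_tfs, cfg$n_clusters))
  cat(sprintf("  noise sd %.2f, dropout %.2f, prior corruption %.2f%s\n",
              cfg$noise_sd, cfg$dropout_p, cfg$prior_corruption,
              if (cfg$cluster_rewire > 0)
                sprintf(", cluster rewiring %.2f", cfg$cluster_rewire)
              else ""))
  invisible(x)
}

#' Simulate a CRISPRi-style TF knockdown
#'
#' Multiplies the true activity of one TF by `factor` in the chosen
#' cells and regenerates expression with the identical noise and
#' dropout streams, so the only difference from the original dataset is
#' the perturbed TF's contribution.
#'
#' @param dataset a `grn_sim`.
#' @param tf TF identifier present in the truth network.
#' @param factor multiplicative knockdown in `[0, 1)` (default 0.1).
#' @param cells cell ids (or indices) to perturb; default all cells.
#' @return A `grn_sim` with modified `truth_activities`, regenerated
#'   `expression`, and a `knockdown` record
#'   (`list(tf, factor, cells)`).
#' @export
simulate_knockdown <- function(dataset, tf, factor = 0.1, cells = NULL) {
  stopifnot(inherits(dataset, "grn_sim"))
  if (!(factor >= 0 && factor < 1)) stop("factor must be in [0, 1)")
  A <- dataset$truth_activities
  if (!tf %in% colnames(A)) stop("unknown TF: ", tf)
  if (is.null(cells)) cells <- rownames(A)
  A[cells, tf] <- A[cells, tf] * factor
  out <- dataset
  out$truth_activities <- A
  lab_num <- as.integer(sub("^C", "", dataset$labels))
  out$expression <- simulate_expression(A, lab_num, dataset$truth_weights,
                                        dataset$config)
  out$knockdown <- list(tf = tf, factor = factor, cells = cells)
  out
}
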