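# Post-hoc analytics on fitted activities and GRNs.

#' Min-max scale a GRN per TF
#'
#' Rescales each TF's outgoing weights to `[0, 1]` by
#' `(w - min) / (max - min)`; constant rows (no dynamic range) map to
#' all zeros.  Scaled weights support relative comparison across TFs
#' and conditions; the raw matrix is kept alongside.
#'
#' @param W TF-by-gene numeric matrix.
#' @return list of class `scaled_grn` with `weights` (scaled) and `raw`.
#' @export
scale_grn <- function(W) {
  W <- as.matrix(W)
  stopifnot_finite(W, "GRN weights")
  rmin <- apply(W, 1, min)
  rmax <- apply(W, 1, max)
  rng <- rmax - rmin
  S <- (W - rmin) / ifelse(rng == 0, 1, rng)
  S[rng == 0, ] <- 0
  structure(list(weights = S, raw = W), class = "scaled_grn")
}

minmax_abs_rows <- function(W) scale_grn(abs(W))$weights

#' Differential TF activity between cell groups
#'
#' For every TF and group, compares in-group activities against all
#' other cells with a two-sided Wilcoxon rank-sum test,
#' Benjamini-Hochberg adjusted across TFs within each group.  Effect
#' size is `log2((mean_in + eps) / (mean_out + eps))`; the retained
#' table keeps TFs with `p_adj < alpha`, ranked by decreasing LFC
#' within each group.
#'
#' @param acts cells x TF activity matrix.
#' @param groups group labels: vector named by cell id or in row order.
#' @param alpha adjusted-p threshold for retention (default 0.05).
#' @param eps pseudo-count guarding against all-zero ReLU activities.
#' @param full if `TRUE`, return every (TF, group) row with a `retained`
#'   flag instead of only the retained ones.
#' @return data.frame with columns `tf`, `group`, `lfc`, `p_raw`,
#'   `p_adj`, `rank` (rank within group among retained rows).
#' @export
differential_tf_activity <- function(acts, groups, alpha = 0.05,
                                     eps = 1e-9, full = FALSE) {
  acts <- as.matrix(acts)
  if (!is.null(names(groups))) {
    if (!all(rownames(acts) %in% names(groups)))
      stop("groups must label every cell")
    groups <- groups[rownames(acts)]
  } else if (length(groups) != nrow(acts)) {
    stop("groups must match the number of cells")
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with < 2 cells: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    acts <- acts[keep, , drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("need at least 2 groups with >= 2 cells each")
  res <- list()
  for (g in sort(unique(groups))) {
    ing <- groups == g
    p <- apply(acts, 2, function(v) {
      if (all(v[ing] == v[ing][1]) && all(v[!ing] == v[ing][1])) return(1)
      suppressWarnings(wilcox.test(v[ing], v[!ing])$p.value)
    })
    lfc <- log2((colMeans(acts[ing, , drop = FALSE]) + eps) /
                  (colMeans(acts[!ing, , drop = FALSE]) + eps))
    res[[g]] <- data.frame(tf = colnames(acts), group = g, lfc = lfc,
                           p_raw = p, p_adj = p.adjust(p, "BH"),
                           row.names = NULL)
  }
  tab <- do.call(rbind, res)
  tab$retained <- tab$p_adj < alpha
  tab <- tab[order(tab$group, -tab$lfc), ]
  tab$rank <- NA_integer_
  for (g in unique(tab$group)) {
    sel <- tab$group == g & tab$retained
    tab$rank[sel] <- seq_len(sum(sel))
  }
  rownames(tab) <- NULL
  if (full) tab else tab[tab$retained,
                        c("tf", "group", "lfc", "p_raw", "p_adj", "rank")]
}

#' TF-TF co-regulation network
#'
#' Links TF pairs whose outgoing regulatory weight vectors have cosine
#' similarity at or above `threshold`.  Zero-norm rows produce no
#' edges; the output is symmetric and excludes self-pairs.
#'
#' @param W TF-by-gene matrix.
#' @param threshold similarity cut-off in `(-1, 1]` (default 0.8).
#' @return data.frame with columns `tf1`, `tf2`, `similarity`
#'   (each unordered pair once).
#' @export
tf_coregulation_network <- function(W, threshold = 0.8) {
  W <- as.matrix(W)
  if (!(threshold > -1 && threshold <= 1))
    stop("threshold must be in (-1, 1]")
  nrm <- sqrt(rowSums(W^2))
  S <- tcrossprod(W) / outer(nrm, nrm)
  S[nrm == 0, ] <- NA; S[, nrm == 0] <- NA
  idx <- which(upper.tri(S) & !is.na(S) & S >= threshold, arr.ind = TRUE)
  tfs <- rownames(W) %||% paste0("TF", seq_len(nrow(W)))
  data.frame(tf1 = tfs[idx[, 1]], tf2 = tfs[idx[, 2]],
             similarity = S[idx])
}

#' Cross-cell-type GRN similarity
#'
#' Each cell type's GRN is taken in absolute value, min-max normalized
#' per TF row, and flattened; pairwise Pearson correlations are then
#' clustered (average linkage on `1 - r`) to reveal groups of cell
#' types with similar regulatory programs.
#'
#' @param grns named list of TF-by-gene matrices sharing dimensions and
#'   dimnames.
#' @return list with `correlation` (symmetric matrix, unit diagonal),
#'   `order` (leaf order of the dendrogram, by name) and `hclust`.
#' @seealso [dendrogram_newick()]
#' @export
grn_similarity <- function(grns) {
  stopifnot(is.list(grns), length(grns) >= 2)
  if (is.null(names(grns))) names(grns) <- paste0("type", seq_along(grns))
  d <- dim(grns[[1]])
  vecs <- sapply(grns, function(M) {
    if (!all(dim(M) == d)) stop("all GRNs must share TF/gene dimensions")
    as.vector(minmax_abs_rows(M))
  })
  sds <- apply(vecs, 2, stats::sd)
  if (any(sds == 0))
    stop("constant GRN vector for cell type: ",
         paste(names(grns)[sds == 0], collapse = ", "))
  R <- cor(vecs)
  hc <- hclust(as.dist(1 - R), method = "average")
  list(correlation = R, order = hc$labels[hc$order], hclust = hc)
}

#' Newick export of a GRN-similarity dendrogram
#'
#' @param similarity result of [grn_similarity()] (or an `hclust`).
#' @return single Newick string.
#' @export
dendrogram_newick <- function(similarity) {
  hc <- if (inherits(similarity, "hclust")) similarity else similarity$hclust
  ape::write.tree(ape::as.phylo(hc))
}

#' Ranked target export per TF
#'
#' Ranks each TF's target genes by (min-max scaled) GRN weight and
#' keeps the top fraction, the conventional input for external
#' enrichment tools.
#'
#' @param W TF-by-gene matrix.
#' @param top_fraction fraction of genes kept per TF (default 0.01).
#' @return data.frame with `tf`, `gene`, `weight` (scaled), `rank`.
#' @export
rank_targets <- function(W, top_fraction = 0.01) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  S <- scale_grn(W)$weights
  n_keep <- max(1L, floor(top_fraction * ncol(S)))
  out <- lapply(rownames(S) %||% paste0("TF", seq_len(nrow(S))),
                function(tf) {
    i <- if (is.null(rownames(S))) as.integer(sub("TF", "", tf)) else tf
    ord <- order(S[i, ], decreasing = TRUE)[seq_len(n_keep)]
    data.frame(tf = tf,
               gene = colnames(S)[ord] %||% as.character(ord),
               weight = S[i, ord], rank = seq_len(n_keep))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
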