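#' Univariate-linear-model TF activity estimates
#'
#' For each cell and TF, regresses the cell's expression vector (across
#' genes) on the TF's prior weight vector and returns the t-statistic of
#' the slope.  This is the classic ULM regulon score: a weighted sum of
#' target-gene expression, standardized by its regression standard
#' error.  Degenerate regressions (zero-variance regressor, i.e. a
#' constant prior column) score 0.  With `nonnegative = TRUE` (the
#' default) each activity is clipped at zero to satisfy the non-negative
#' TF-activity convention used for blending and reporting; raw
#' t-statistics are returned with `nonnegative = FALSE`.
#'
#' @param expr an `expression_matrix` (or matrix), cells x genes.
#' @param prior a `prior_grn` (or TF-by-gene matrix) whose gene order
#'   matches `expr` exactly.
#' @param nonnegative clip activities at 0 (default `TRUE`).
#' @return cells x TF numeric matrix with dimnames.
#' @export
ulm_activities <- function(expr, prior, nonnegative = TRUE) {
  expr <- as_expression_matrix(expr)
  if (!inherits(prior, "prior_grn")) prior <- prior_grn(prior)
  if (!identical(expr$gene_ids, prior$gene_ids))
    stop("gene order of expression and prior must be identical")
  X <- expr$values                      # n_cells x G
  W <- as.matrix(prior$weights)         # K x G
  if (any(Matrix::rowSums(prior$weights != 0) == 0))
    stop("prior contains an all-zero TF row; filter the prior first")
  G <- ncol(X)
  if (G < 3) stop("need at least 3 genes for a slope t-statistic")

  Wc <- W - rowMeans(W)                 # center regressors per TF
  Sww <- rowSums(Wc^2)                  # K
  Xc <- X - rowMeans(X)                 # center each cell's profile
  Sxx <- rowSums(Xc^2)                  # n
  Sxw <- Xc %*% t(Wc)                   # n x K
  b <- sweep(Sxw, 2, Sww, "/")          # slopes
  b[, Sww == 0] <- 0
  rss <- pmax(Sxx - sweep(b^2, 2, Sww, "*"), 0)
  se2 <- sweep(rss / (G - 2), 2, Sww, "/")
  tstat <- b / sqrt(pmax(se2, .Machine$double.xmin))
  tstat[, Sww == 0] <- 0
  tstat[!is.finite(tstat)] <- 0
  dimnames(tstat) <- list(expr$cell_ids, prior$tf_ids)
  if (nonnegative) tstat <- relu(tstat)
  tstat
}
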