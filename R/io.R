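#' Construct an expression matrix container
#'
#' Wraps a cells-by-genes numeric matrix with identifier checks.  Values
#' may be raw counts or log-normalized expression; the `is_lognorm` flag
#' records which, so downstream code can decide whether to normalize.
#'
#' @param values numeric matrix, cells in rows, genes in columns, with
#'   row and column names.  All values must be finite and non-negative.
#' @param is_lognorm logical; `TRUE` if `values` are already
#'   log-normalized.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `is_lognorm`.
#' @export
expression_matrix <- function(values, is_lognorm = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have cell (row) and gene (column) names")
  stopifnot_finite(values, "expression matrix")
  if (min(values) < 0)
    stop("expression values must be non-negative")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene identifiers")
  structure(list(values = values,
                 cell_ids = rownames(values),
                 gene_ids = colnames(values),
                 is_lognorm = isTRUE(is_lognorm)),
            class = "expression_matrix")
}

as_expression_matrix <- function(x, is_lognorm = FALSE) {
  if (inherits(x, "expression_matrix")) return(x)
  expression_matrix(x, is_lognorm = is_lognorm)
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes (%s)\n",
              length(x$cell_ids), length(x$gene_ids),
              if (x$is_lognorm) "log-normalized" else "counts"))
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Supports MatrixMarket triplets with companion gene/barcode files (the
#' usual CellRanger layout, genes in rows) and dense delimited files with
#' cells in rows and genes in columns (first column = cell identifiers).
#'
#' @param path path to a `.mtx`, `.csv` or `.tsv`/`.txt` file.
#' @param genes_file,cells_file for MTX input, paths to one-column text
#'   files naming rows and columns; default to `genes.tsv` /
#'   `barcodes.tsv` next to `path`.
#' @param mtx_genes_in_rows logical; MTX convention (genes x cells,
#'   transposed on load). Default `TRUE`.
#' @param is_lognorm see [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, genes_file = NULL, cells_file = NULL,
                                   mtx_genes_in_rows = TRUE,
                                   is_lognorm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes_file <- genes_file %||% file.path(dir, "genes.tsv")
    cells_file <- cells_file %||% file.path(dir, "barcodes.tsv")
    genes <- read.table(genes_file, sep = "\t", stringsAsFactors = FALSE)[[1]]
    cells <- read.table(cells_file, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (mtx_genes_in_rows) {
      rownames(m) <- genes; colnames(m) <- cells
      m <- t(m)
    } else {
      rownames(m) <- cells; colnames(m) <- genes
    }
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                     check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
  }
  expression_matrix(m, is_lognorm = is_lognorm)
}

#' Write an expression matrix as MatrixMarket triplets
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv` and `barcodes.tsv`
#' into `dir`.
#'
#' @param expr an `expression_matrix`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(expr, dir) {
  expr <- as_expression_matrix(expr)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(t(expr$values), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(expr$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(expr$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Library-size normalize and log-transform counts
#'
#' Convenience `log1p(CPM)`-style transform for raw counts: each cell is
#' scaled to `scale` total counts, then `log1p` is applied.  Cells with
#' zero total are left at zero.
#'
#' @param expr an `expression_matrix` (or matrix) of counts.
#' @param scale target per-cell total (default `1e4`).
#' @return An `expression_matrix` with `is_lognorm = TRUE`.
#' @export
lognorm_cpm <- function(expr, scale = 1e4) {
  expr <- as_expression_matrix(expr)
  tot <- rowSums(expr$values)
  tot[tot == 0] <- 1
  expression_matrix(log1p(expr$values / tot * scale), is_lognorm = TRUE)
}

#' Construct a prior GRN container
#'
#' @param weights TF-by-gene matrix (dense or `Matrix` sparse) with
#'   entries in `{-1, 0, +1}` (ternary) or `{0, 1}` (binary); dimnames
#'   required.
#' @return An object of class `prior_grn`: list with `tf_ids`,
#'   `gene_ids`, and sparse `weights`.
#' @export
prior_grn <- function(weights) {
  w <- Matrix::Matrix(as(weights, "matrix"), sparse = TRUE)
  if (is.null(rownames(w)) || is.null(colnames(w)))
    stop("prior weights must carry TF (row) and gene (column) names")
  if (anyDuplicated(rownames(w)) || anyDuplicated(colnames(w)))
    stop("duplicate TF or gene identifiers in prior")
  vals <- unique(as.vector(w@x))
  if (length(vals) && !all(vals %in% c(-1, 0, 1)))
    stop("prior weights must be in {-1, 0, +1}")
  structure(list(tf_ids = rownames(w), gene_ids = colnames(w), weights = w),
            class = "prior_grn")
}

#' @exportS3Method base::print
print.prior_grn <- function(x, ...) {
  nz <- Matrix::nnzero(x$weights)
  cat(sprintf("prior_grn: %d TFs x %d genes, %d edges\n",
              length(x$tf_ids), length(x$gene_ids), nz))
  invisible(x)
}

#' Load a signed prior GRN from a TF-target edge list
#'
#' Reads a headered delimited file with columns `source` (TF), `target`
#' (gene) and optionally `weight` (sign); builds the sparse TF-by-gene
#' prior matrix.  Duplicate (TF, gene) edges are collapsed by sign
#' majority, with ties resolved to `+1`.  TF and gene order follow first
#' appearance in the file.
#'
#' @param path path to a TSV/CSV edge list.
#' @param sign_mode `"ternary"` keeps signs in `{-1, +1}`; `"binary"`
#'   collapses every edge to `+1`.
#' @param sep field separator (default tab).
#' @return A `prior_grn`.
#' @export
load_prior_edges <- function(path, sign_mode = c("ternary", "binary"),
                             sep = "\t") {
  sign_mode <- match.arg(sign_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
               fill = FALSE),
    error = function(e) stop("malformed edge list '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0) stop("empty prior edge list: ", path)
  if (ncol(df) < 2) stop("edge list needs at least (source, target) columns")
  src <- as.character(df[[1]]); tgt <- as.character(df[[2]])
  w <- if (ncol(df) >= 3) suppressWarnings(as.numeric(df[[3]])) else rep(1, nrow(df))
  bad <- which(is.na(src) | is.na(tgt) | src == "" | tgt == "" | is.na(w) | w == 0)
  if (length(bad))
    stop(sprintf("malformed edge list row %d (after header) in '%s'",
                 bad[1], path))
  sgn <- sign(w)
  tf_ids <- unique(src); gene_ids <- unique(tgt)
  key <- paste(src, tgt, sep = "\r")
  # collapse duplicates by sign majority; ties -> +1
  agg <- tapply(sgn, key, sum)
  ks <- strsplit(names(agg), "\r", fixed = TRUE)
  esrc <- vapply(ks, `[`, "", 1L)
  etgt <- vapply(ks, `[`, "", 2L)
  esgn <- as.numeric(ifelse(agg > 0, 1, ifelse(agg < 0, -1, 1)))
  if (sign_mode == "binary") esgn <- rep(1, length(esgn))
  w <- Matrix::sparseMatrix(i = match(esrc, tf_ids),
                            j = match(etgt, gene_ids),
                            x = esgn,
                            dims = c(length(tf_ids), length(gene_ids)),
                            dimnames = list(tf_ids, gene_ids))
  prior_grn(w)
}

#' Write a prior GRN as a TF-target edge list
#'
#' Inverse of [load_prior_edges()]: writes the nonzero entries as a
#' headered TSV with columns `source`, `target`, `weight`.
#'
#' @param prior a `prior_grn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prior_edges <- function(prior, path) {
  stopifnot(inherits(prior, "prior_grn"))
  tw <- Matrix::mat2triplet(prior$weights)
  keep <- tw$x != 0
  ord <- order(tw$i[keep], tw$j[keep])
  df <- data.frame(source = prior$tf_ids[tw$i[keep]][ord],
                   target = prior$gene_ids[tw$j[keep]][ord],
                   weight = tw$x[keep][ord])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jointly filter and align expression and prior GRN
#'
#' Applies the standard joint filters before model fitting: genes must be
#' expressed (value strictly greater than zero) in at least
#' `min_cells_per_gene` cells *and* have at least one regulating TF in
#' the prior; cells must express at least `min_genes_per_cell` retained
#' genes; TFs must regulate at least `min_targets_per_tf` retained
#' genes.  Filters are applied in that order (genes, cells, TFs), then a
#' single re-check pass is made so that genes orphaned by TF removal are
#' dropped and the TF filter is re-evaluated once.  The returned prior
#' shares the expression matrix's gene order.
#'
#' @param expr an `expression_matrix` (or matrix).
#' @param prior a `prior_grn` (or TF-by-gene matrix).
#' @param min_cells_per_gene minimum cells a gene must be expressed in
#'   (default 10).
#' @param min_genes_per_cell minimum retained genes a cell must express
#'   (default 3).
#' @param min_targets_per_tf minimum retained targets a TF must keep
#'   (default 10).
#' @param uppercase_genes if `TRUE`, gene and TF symbols on both sides
#'   are uppercased before matching (human-symbol convenience); matching
#'   is otherwise exact and case-sensitive.
#' @return An `aligned_dataset`: list with `expression`, `prior`,
#'   `train_index`, `val_index` (the index slots are `NULL` until
#'   [split_train_val()] is applied).
#' @export
filter_and_align <- function(expr, prior,
                             min_cells_per_gene = 10,
                             min_genes_per_cell = 3,
                             min_targets_per_tf = 10,
                             uppercase_genes = FALSE) {
  expr <- as_expression_matrix(expr)
  if (!inherits(prior, "prior_grn")) prior <- prior_grn(prior)
  X <- expr$values
  P <- prior$weights
  if (uppercase_genes) {
    colnames(X) <- toupper(colnames(X))
    colnames(P) <- toupper(colnames(P))
    rownames(P) <- toupper(rownames(P))
  }

  genes <- colnames(X)
  cells <- rownames(X)
  tfs <- rownames(P)

  gene_pass <- function(X, P, genes, cells, tfs) {
    expressed <- colSums(X[cells, genes, drop = FALSE] > 0) >= min_cells_per_gene
    in_prior <- genes %in% colnames(P)
    has_tf <- rep(FALSE, length(genes))
    hit <- which(in_prior)
    if (length(hit) && length(tfs))
      has_tf[hit] <- Matrix::colSums(
        P[tfs, genes[hit], drop = FALSE] != 0) >= 1
    genes[expressed & has_tf]
  }
  cell_pass <- function(X, genes, cells) {
    cells[rowSums(X[cells, genes, drop = FALSE] > 0) >= min_genes_per_cell]
  }
  tf_pass <- function(P, genes, tfs) {
    if (!length(genes)) return(character(0))
    tfs[Matrix::rowSums(P[tfs, intersect(genes, colnames(P)),
                          drop = FALSE] != 0) >= min_targets_per_tf]
  }

  # first pass: genes -> cells -> TFs, then one re-check pass
  for (pass in 1:2) {
    genes <- gene_pass(X, P, genes, cells, tfs)
    if (!length(genes))
      stop("no genes survive the gene filter (expression/prior coverage)")
    cells <- cell_pass(X, genes, cells)
    if (!length(cells))
      stop("no cells survive the cell filter (min genes per cell)")
    tfs <- tf_pass(P, genes, tfs)
    if (!length(tfs))
      stop("no TFs survive the TF filter (min targets per TF)")
  }

  out_expr <- expression_matrix(X[cells, genes, drop = FALSE],
                                is_lognorm = expr$is_lognorm)
  out_prior <- prior_grn(P[tfs, genes, drop = FALSE])
  structure(list(expression = out_expr, prior = out_prior,
                 train_index = NULL, val_index = NULL),
            class = "aligned_dataset")
}

#' @exportS3Method base::print
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("aligned_dataset: %d cells x %d genes, %d TFs",
              length(x$expression$cell_ids), length(x$expression$gene_ids),
              length(x$prior$tf_ids)))
  if (!is.null(x$train_index))
    cat(sprintf(" (train %d / val %d)", length(x$train_index),
                length(x$val_index)))
  cat("\n")
  invisible(x)
}

#' Split cells into training and validation sets
#'
#' Seeded uniform shuffle; the validation size is
#' `round(val_fraction * n)` clamped to `[1, n - 1]`.
#'
#' @param data an `aligned_dataset`.
#' @param val_fraction fraction of cells held out (default 0.15).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return `data` with `train_index` and `val_index` filled in
#'   (disjoint, jointly exhaustive, sorted).
#' @export
split_train_val <- function(data, val_fraction = 0.15, seed = 42) {
  stopifnot(inherits(data, "aligned_dataset"))
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must be in (0, 1)")
  n <- length(data$expression$cell_ids)
  if (n < 2) stop("need at least 2 cells to split")
  n_val <- min(max(round(val_fraction * n), 1L), n - 1L)
  perm <- with_seed(seed, sample.int(n))
  data$val_index <- sort(perm[seq_len(n_val)])
  data$train_index <- sort(perm[-seq_len(n_val)])
  data
}
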