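test_that("dropout masking zeroes the expected fraction, deterministically", {
  d <- make_tiny_dataset(n_cells = 500, n_genes = 200)
  em <- expression_matrix(d$X + 1)   # all entries nonzero
  expect_identical(dropout_mask(em, 0, seed = 1)$values, em$values)
  p <- 0.3
  masked <- dropout_mask(em, p, seed = 4)
  n <- length(em$values)
  frac <- mean(masked$values == 0)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  expect_identical(masked$values, dropout_mask(em, p, seed = 4)$values)
  expect_error(dropout_mask(em, 1), "\\[0, 1\\)")
})

test_that("two well-separated blobs are recovered at moderate resolution", {
  set.seed(31)
  acts <- rbind(matrix(rnorm(300, 0, 0.3), 100, 3),
                matrix(rnorm(300, 5, 0.3), 100, 3))
  acts <- pmax(acts, 0)
  rownames(acts) <- paste0("c", 1:200)
  truth <- rep(c("A", "B"), each = 100)
  cls <- cluster_activities(acts, resolutions = c(0.2, 1.0), seed = 2)
  expect_named(cls, c("0.2", "1"))
  m <- cls[["1"]]
  expect_identical(m, cluster_activities(acts, resolutions = 1, seed = 2)[[1]])
  assigned <- majority_vote_labels(m, truth)
  expect_equal(unname(assigned), truth)
  expect_error(cluster_activities(acts, resolutions = c(1, -1)), "positive")
  # default sweep spans 0.2 through 3.0
  expect_equal(range(eval(formals(cluster_activities)$resolutions)),
               c(0.2, 3.0))
})

test_that("majority voting assigns modal labels with lexicographic ties", {
  pred <- c(1, 1, 1, 1, 1)
  truth <- c("A", "A", "A", "B", "B")
  expect_equal(unname(majority_vote_labels(pred, truth)), rep("A", 5))
  expect_equal(unname(majority_vote_labels(c(1, 1, 1, 1), c("B", "B", "A", "A"))),
               rep("A", 4))
  # clusters identical to the truth partition reproduce the truth
  truth2 <- rep(c("x", "y"), each = 3)
  expect_equal(unname(majority_vote_labels(rep(1:2, each = 3), truth2)), truth2)
})

test_that("clustering metrics hit their closed-form fixtures", {
  truth <- rep(c("A", "B"), each = 10)
  r <- clustering_metrics(truth, truth)
  expect_equal(r$ari, 1); expect_equal(r$nmi, 1)
  expect_equal(r$macro_f1, 1); expect_equal(r$auc, 1)

  # hand-worked 4-cell contingency: {(A->A):2, (B->A):1, (B->B):1}
  r2 <- clustering_metrics(c("A", "A", "A", "B"), c("A", "A", "B", "B"))
  expect_equal(r2$macro_f1, 11 / 15)

  # random balanced labels have ARI near zero
  set.seed(33)
  big_truth <- rep(c("A", "B"), 1000)
  perm <- sample(big_truth)
  expect_lt(abs(clustering_metrics(perm, big_truth)$ari), 0.05)

  expect_error(clustering_metrics(truth, rep("A", 20)), "single")
})

test_that("ARI is invariant to label permutation and NMI is symmetric", {
  set.seed(34)
  a <- sample(letters[1:3], 60, replace = TRUE)
  b <- sample(LETTERS[1:4], 60, replace = TRUE)
  relab <- c(a = "z", b = "q", c = "m")[a]
  expect_equal(clustering_metrics(a, b)$ari, clustering_metrics(relab, b)$ari)
  expect_equal(clustering_metrics(a, b)$nmi, clustering_metrics(b, a)$nmi)
})

test_that("GRN AUROC/AUPRC match the exhaustive threshold sweep", {
  truth <- c(1, 1, 0, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  got <- grn_auroc_auprc(rbind(scores), rbind(truth))
  want <- sweep_roc_pr(scores, truth)
  expect_equal(got$auroc, want$auroc)
  expect_equal(got$auprc, want$auprc)

  # perfect and constant predictors hit their theoretical values
  perfect <- grn_auroc_auprc(rbind(truth), rbind(truth))
  expect_equal(perfect$auroc, 1); expect_equal(perfect$auprc, 1)
  const <- grn_auroc_auprc(rbind(rep(0.5, 6)), rbind(truth))
  expect_equal(const$auroc, 0.5)
  expect_equal(const$auprc, mean(truth))

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:1000, 1)
    s <- round(runif(n), sample(1:3, 1))   # force ties
    y <- rbinom(n, 1, 0.3)
    if (sum(y) == 0 || sum(y) == n) next
    got <- grn_auroc_auprc(rbind(s), rbind(y))
    want <- sweep_roc_pr(s, y)
    expect_equal(got$auroc, want$auroc, tolerance = 1e-12)
    expect_equal(got$auprc, want$auprc, tolerance = 1e-12)
  }
  expect_error(grn_auroc_auprc(rbind(scores), rbind(rep(1, 6))), "constant")
})

test_that("evaluation respects the TF/gene intersection", {
  pred <- matrix(runif(12), 3, 4,
                 dimnames = list(c("t1", "t2", "t3"), paste0("g", 1:4)))
  truth <- matrix(rbinom(6, 1, 0.5), 2, 3,
                  dimnames = list(c("t2", "t3"), c("g2", "g3", "g4")))
  truth[1, 1] <- 1; truth[2, 1] <- 0
  r <- grn_auroc_auprc(pred, truth)
  expect_equal(r$n, 6)
})

test_that("stratified sketching splits clusters proportionally", {
  d <- make_tiny_dataset(n_cells = 100, n_genes = 10)
  clusters <- rep(1:3, times = c(50, 30, 20))
  subs <- stratified_sketch(expression_matrix(d$X + 1), n_subsets = 5,
                            seed = 1, clusters = clusters)
  expect_length(subs, 5)
  expect_setequal(unlist(subs), 1:100)
  expect_equal(sum(lengths(subs)), 100)
  for (s in subs) {
    tab <- table(clusters[s])
    expect_equal(as.numeric(tab), c(10, 6, 4))
  }
  # pairwise disjoint
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(subs[[i]], subs[[j]]), 0)
  expect_error(stratified_sketch(expression_matrix(d$X[1:3, ] + 1),
                                 n_subsets = 5, clusters = 1:3),
               "more subsets")
})

test_that("sketching on raw expression discovers pseudo-clusters itself", {
  set.seed(36)
  X <- rbind(matrix(rnorm(600, 0, 0.3), 60, 10),
             matrix(rnorm(400, 6, 0.3), 40, 10))
  X <- pmax(X, 0)
  dimnames(X) <- list(paste0("c", 1:100), paste0("g", 1:10))
  subs <- stratified_sketch(expression_matrix(X), n_subsets = 4, seed = 3)
  expect_setequal(unlist(subs), 1:100)
  # each subset keeps roughly the 60/40 composition (within one cell)
  for (s in subs) {
    frac <- mean(s <= 60)
    expect_lt(abs(frac - 0.6), 0.1)
  }
})

test_that("knockdown evaluation computes LFC and rank-sum significance", {
  set.seed(37)
  ctrl <- matrix(abs(rnorm(100, 4)), 50, 2,
                 dimnames = list(NULL, c("tfA", "tfB")))
  same <- knockdown_evaluation(ctrl, ctrl, "tfA")
  expect_equal(same$lfc, 0)
  expect_gt(same$p_value, 0.9)
  half <- ctrl; half[, "tfA"] <- ctrl[, "tfA"] * 0.5
  r <- knockdown_evaluation(ctrl, half, "tfA")
  expect_equal(r$lfc, -1, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-6)
  expect_error(knockdown_evaluation(ctrl, half, "missing"), "not present")
  scr <- knockdown_screen(ctrl, half)
  expect_equal(scr$tf, c("tfA", "tfB"))
  expect_true(all(scr$p_adj >= scr$p_value))
})

test_that("ROC/PR and ARI agree with independent reference implementations", {
  skip_if_not_installed("pROC")
  skip_if_not_installed("mclust")
  set.seed(38)
  scores <- round(runif(300), 2)
  y <- rbinom(300, 1, 0.4)
  got <- grn_auroc_auprc(rbind(scores), rbind(y))
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got$auroc, ref, tolerance = 1e-12)
  a <- sample(1:4, 200, replace = TRUE)
  b <- sample(1:3, 200, replace = TRUE)
  expect_equal(clustering_metrics(a, b)$ari,
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
})
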