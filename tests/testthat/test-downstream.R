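test_that("per-TF min-max scaling maps rows to [0,1] with degenerate rows at 0", {
  W <- rbind(a = c(-2, 0, 2), b = c(3, 3, 3), c = c(0, 0.5, 1))
  s <- scale_grn(W)
  expect_equal(unname(s$weights["a", ]), c(0, 0.5, 1))
  expect_equal(unname(s$weights["b", ]), c(0, 0, 0))
  expect_equal(s$weights["c", ], W["c", ])
  expect_true(all(s$weights >= 0 & s$weights <= 1))
  # invariance to positive affine transforms of a row
  s2 <- scale_grn(rbind(a = 3 * W["a", ] + 7))
  expect_equal(unname(s2$weights[1, ]), unname(s$weights["a", ]))
})

test_that("differential TF activity retains shifted TFs and ranks by LFC", {
  set.seed(14)
  n <- 60
  acts <- cbind(up = c(rnorm(n, 5), rnorm(n, 1)),
                flat = rep(2, 2 * n),
                dn = c(rnorm(n, 1), rnorm(n, 5)))
  acts <- pmax(acts, 0)
  rownames(acts) <- paste0("c", seq_len(2 * n))
  groups <- rep(c("A", "B"), each = n)
  tab <- differential_tf_activity(acts, groups, full = TRUE)
  flatA <- tab[tab$tf == "flat" & tab$group == "A", ]
  expect_equal(flatA$lfc, 0)
  expect_false(flatA$retained)
  upA <- tab[tab$tf == "up" & tab$group == "A", ]
  expect_true(upA$retained && upA$lfc > 0 && upA$p_adj < 0.05)
  ret <- differential_tf_activity(acts, groups)
  rA <- ret[ret$group == "A", ]
  expect_equal(rA$rank, seq_len(nrow(rA)))
  expect_true(all(diff(rA$lfc) <= 0))
})

test_that("differential testing is invariant to common positive rescaling", {
  set.seed(15)
  acts <- matrix(abs(rnorm(80)), 40, 2,
                 dimnames = list(paste0("c", 1:40), c("t1", "t2")))
  groups <- rep(c("A", "B"), 20)
  t1 <- differential_tf_activity(acts, groups, full = TRUE)
  t2 <- differential_tf_activity(acts * 7, groups, full = TRUE)
  expect_equal(t1$p_raw, t2$p_raw)
  expect_equal(t1$lfc, t2$lfc, tolerance = 1e-6)
})

test_that("small groups are excluded with a warning", {
  acts <- matrix(1:12, 6, 2,
                 dimnames = list(paste0("c", 1:6), c("t1", "t2")))
  expect_warning(differential_tf_activity(acts, c("A", "A", "A", "B", "B", "C")),
                 "excluding")
})

test_that("co-regulation edges follow cosine similarity", {
  W <- rbind(a = c(1, 2, 0), b = c(2, 4, 0), c = c(0, 0, 5),
             d = -c(1, 2, 0), e = c(0, 0, 0))
  net <- tf_coregulation_network(W, threshold = 0.99)
  expect_equal(nrow(net), 1)
  expect_setequal(unlist(net[1, c("tf1", "tf2")]), c("a", "b"))
  expect_equal(net$similarity, 1)
  # orthogonal and opposite rows never link; zero rows produce no edge
  net2 <- tf_coregulation_network(W, threshold = -0.5)
  expect_false(any((net2$tf1 == "a" & net2$tf2 == "d")))
  expect_false("e" %in% c(net2$tf1, net2$tf2))
  # invariant to positive row scaling
  net3 <- tf_coregulation_network(W * 3, threshold = 0.99)
  expect_equal(net3, net)
})

test_that("GRN similarity is sign-blind, symmetric, and clusters likes", {
  set.seed(16)
  base <- matrix(rnorm(60), 6, 10,
                 dimnames = list(paste0("tf", 1:6), paste0("g", 1:10)))
  near <- base; near[1, 1] <- near[1, 1] + 0.2      # ~90% shared structure
  far <- matrix(rnorm(60), 6, 10, dimnames = dimnames(base))
  gs <- grn_similarity(list(A = base, B = near, C = far))
  expect_equal(gs$correlation, t(gs$correlation))
  expect_equal(unname(diag(gs$correlation)), rep(1, 3))
  expect_equal(unname(gs$correlation["A", "B"]),
               unname(max(gs$correlation[upper.tri(gs$correlation)])))
  # the first merge joins the similar pair
  first <- gs$hclust$labels[-gs$hclust$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  # negation is identical after the absolute-value normalization
  gneg <- grn_similarity(list(A = base, B = -base, C = far))
  expect_equal(unname(gneg$correlation["A", "B"]), 1)
  expect_error(grn_similarity(list(A = base, B = base * 0 + 1)), "constant")
})

test_that("newick export reflects the dendrogram leaves", {
  set.seed(17)
  mats <- lapply(1:3, function(i) matrix(rnorm(40), 4, 10))
  names(mats) <- c("x", "y", "z")
  gs <- grn_similarity(mats)
  nwk <- dendrogram_newick(gs)
  expect_match(nwk, "^\\(")
  for (nm in names(mats)) expect_match(nwk, nm)
})

test_that("top-target export keeps the right number per TF, ranked", {
  set.seed(18)
  W <- matrix(rnorm(300), 3, 100,
              dimnames = list(paste0("tf", 1:3), paste0("g", 1:100)))
  tt <- rank_targets(W, top_fraction = 0.05)
  expect_equal(nrow(tt), 15)
  for (tf in rownames(W)) {
    sub <- tt[tt$tf == tf, ]
    expect_equal(nrow(sub), 5)
    expect_true(all(diff(sub$weight) <= 0))
    expect_equal(sub$gene[1], names(which.max(scale_grn(W)$weights[tf, ])))
  }
})
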