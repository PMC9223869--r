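test_that("fingerprints share the pair index and conserve the descriptor", {
  confs <- make_synthetic_conformers(2, 2, 2, seed = 12)
  fp <- pair_fingerprints(confs, lag = 5, scheme = "m")
  expect_equal(nrow(fp), 6L)
  expect_true(all(fp >= 0))
  # row sums equal the per-conformer HATS5m
  for (c in seq_along(confs)) {
    v <- coef(hats_profile(confs[[c]], "m", 5))["m", "5"]
    expect_equal(unname(rowSums(fp)[c]), v, tolerance = 1e-12)
    expect_equal(unname(attr(fp, "values")[c]), v, tolerance = 1e-12)
  }
  # identical-geometry conformers give identical vectors
  twins <- list(confs[[1L]], confs[[1L]])
  fp2 <- pair_fingerprints(twins, lag = 5)
  expect_equal(fp2[1L, ], fp2[2L, ])
  # bent vs extended chains differ in long-range pair entries
  expect_gt(max(abs(fp["linear1", ] - fp["U1", ])), 0)
})

test_that("topology mismatch across conformers is a named error", {
  a <- make_n_alkane(6)
  b <- make_n_alkane(6)
  expect_silent(pair_fingerprints(list(a, b), lag = 3))
  c <- make_n_alkane(6)
  c$bonds <- c$bonds[-3L, ]
  expect_error(pair_fingerprints(list(a, c), lag = 3), "differing bond")
  d <- make_n_alkane(6)
  d$elements[2L] <- "O"
  expect_error(pair_fingerprints(list(a, d), lag = 3), "element sequence")
})

test_that("normalized fingerprints have unit row sums", {
  confs <- make_synthetic_conformers(2, 2, 0, seed = 4)
  fp <- pair_fingerprints(confs, lag = 5, normalize = TRUE)
  expect_equal(unname(rowSums(fp)), rep(1, 4L))
})

test_that("UPGMA merges in the forced order on a separable triple", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3L)
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  den <- upgma(stats::as.dist(d))
  expect_equal(sort(den$hclust$height), c(1, 10))
  expect_equal(as.matrix(den$cophenetic)["a", "b"], 1)
  expect_equal(as.matrix(den$cophenetic)["a", "c"], 10)
})

test_that("UPGMA reproduces ultrametric input exactly (CCC = 1)", {
  # build an ultrametric: two tight pairs joined higher
  u <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 2,
                5, 5, 2, 0), 4L)
  den <- upgma(stats::as.dist(u))
  expect_equal(as.matrix(den$cophenetic), u, ignore_attr = TRUE)
  expect_equal(cophenetic_correlation(den), 1)
})

test_that("UPGMA merge heights match the naive agglomeration oracle", {
  set.seed(61)
  for (rep in 1:5) {
    pts <- matrix(stats::rnorm(16L), 8L)
    d <- stats::dist(pts)
    den <- upgma(d)
    expect_equal(sort(den$hclust$height), sort(upgma_naive_heights(d)),
                 tolerance = 1e-12)
  }
})

test_that("cophenetic correlation equals brute-force Pearson and rejects degenerates", {
  set.seed(19)
  pts <- matrix(stats::rnorm(20L), 10L)
  d <- stats::dist(pts)
  den <- upgma(d)
  expect_equal(cophenetic_correlation(den),
               stats::cor(as.vector(d), as.vector(den$cophenetic)))
  # n = 2: a single distance pair has no correlation
  d2 <- stats::dist(matrix(stats::rnorm(4L), 2L))
  expect_error(cophenetic_correlation(upgma(d2)), "undefined")
  # zero-variance distances
  d0 <- stats::as.dist(matrix(1, 3L, 3L) - diag(3L))
  expect_error(cophenetic_correlation(upgma(d0)), "zero-variance")
  expect_error(upgma(stats::as.dist(matrix(NaN, 2, 2))), "NA")
})

test_that("three planted shape classes are recovered at the 3-cluster cut", {
  confs <- make_synthetic_conformers(6, 6, 6, seed = 2)
  fp <- pair_fingerprints(confs, lag = 5, scheme = "m")
  rep3 <- shape_report(fp, n_clusters = 3)
  truth <- sub("[0-9]+$", "", names(confs))
  expect_equal(length(unique(rep3$assignments)), 3L)
  # each planted class maps to exactly one recovered cluster
  expect_true(all(tapply(rep3$assignments, truth,
                         function(g) length(unique(g))) == 1L))
  expect_equal(length(unique(tapply(rep3$assignments, truth, unique))), 3L)
  expect_true(rep3$ccc > 0 && rep3$ccc <= 1)
  # degenerate cuts
  expect_equal(length(unique(shape_report(fp, n_clusters = 1)$assignments)), 1L)
  singles <- shape_report(fp, n_clusters = nrow(fp))
  expect_equal(length(unique(singles$assignments)), nrow(fp))
  expect_error(shape_report(fp, n_clusters = 3, height = 1), "exactly one")
})

test_that("cluster partition is stable under conformer input permutation", {
  confs <- make_synthetic_conformers(4, 4, 4, seed = 9)
  fp1 <- pair_fingerprints(confs, lag = 5)
  set.seed(1); perm <- sample(length(confs))
  fp2 <- pair_fingerprints(confs[perm], lag = 5)
  a1 <- shape_report(fp1, n_clusters = 3)$assignments
  a2 <- shape_report(fp2, n_clusters = 3)$assignments
  # same partition up to label renaming
  expect_equal(length(unique(paste(a1[names(a2)], a2))),
               length(unique(a1)))
})

test_that("scaling fingerprints scales heights and preserves CCC", {
  confs <- make_synthetic_conformers(3, 3, 3, seed = 5)
  fp <- pair_fingerprints(confs, lag = 5)
  den1 <- upgma(fp)
  fp10 <- fp
  fp10[] <- fp * 10
  den10 <- upgma(fp10)
  expect_equal(den10$hclust$height, den1$hclust$height * 10,
               tolerance = 1e-12)
  expect_equal(cophenetic_correlation(den10), cophenetic_correlation(den1),
               tolerance = 1e-12)
})

test_that("newick export round-trips through ape with the right leaves", {
  confs <- make_synthetic_conformers(2, 2, 1, seed = 3)
  den <- upgma(pair_fingerprints(confs, lag = 5))
  nwk <- as_newick(den)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, names(confs))
})

test_that("fragment-aggregated cluster profiles sum to the pair profiles", {
  confs <- make_synthetic_conformers(3, 3, 0, seed = 21)
  ref <- confs[[1L]]
  labs <- ifelse(ref$elements == "C" & seq_len(n_atoms(ref)) <= 5, "head",
                 "rest")
  part <- fragment_partition(labs, ref)
  fp <- pair_fingerprints(confs, lag = 5)
  rep2 <- shape_report(fp, n_clusters = 2, partition = part)
  expect_equal(unname(rowSums(rep2$fragment_profiles)),
               unname(rowSums(rep2$profiles)), tolerance = 1e-12)
})
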