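test_that("single-fragment partition puts the whole value in one intra cell", {
  mol <- make_halide_probe("Cl")
  h <- hats_profile(mol, "m", 5)
  part <- fragment_partition(rep("core", n_atoms(mol)), mol)
  dec <- fragment_decompose(h, part, lag = 5)
  expect_equal(dim(dec$matrix), c(1L, 1L))
  expect_equal(dec$matrix["core", "core"], dec$total)
})

test_that("a two-atom molecule splits entirely into the inter cell at lag 1", {
  m <- molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                bonds = rbind(c(1, 2)), check_h = FALSE)
  h <- hats_profile(m, "m", 1)
  dec <- fragment_decompose(h, fragment_partition(c("a", "b"), m), lag = 1)
  expect_equal(dec$matrix["a", "b"], dec$total)
  expect_equal(dec$matrix["a", "a"], 0)
  expect_equal(dec$matrix["b", "b"], 0)
})

test_that("cells match brute-force re-binning on random partitions", {
  set.seed(17)
  for (rep in 1:8) {
    mol <- random_molecule(15L)
    labs <- sample(c("A", "B", "C"), 15L, replace = TRUE)
    part <- fragment_partition(labs, mol)
    h <- hats_profile(mol, "m", 0:4)
    for (k in 0:4) {
      dec <- fragment_decompose(h, part, lag = k)
      p <- h$pairs$m[[as.character(k)]]
      for (a in dec$labels) for (b in dec$labels) {
        fi <- labs[p$i]; fj <- labs[p$j]
        want <- sum(p$value[(fi == a & fj == b) | (fi == b & fj == a)])
        expect_equal(dec$matrix[a, b], want, tolerance = 1e-12)
      }
      # exact partition of summands
      ut <- dec$matrix[upper.tri(dec$matrix, diag = TRUE)]
      expect_equal(sum(ut), dec$total, tolerance = 1e-12 * max(1, dec$total))
    }
  }
})

test_that("decomposition respects label renaming and fragment merging", {
  set.seed(23)
  mol <- random_molecule(18L)
  labs <- sample(c("p", "q", "r"), 18L, replace = TRUE)
  h <- hats_profile(mol, "m", 3)
  fine <- fragment_decompose(h, fragment_partition(labs, mol), lag = 3)
  # renaming
  ren <- c(p = "x", q = "y", r = "z")
  dec2 <- fragment_decompose(h, fragment_partition(ren[labs], mol), lag = 3)
  expect_equal(unname(dec2$matrix[ren[fine$labels], ren[fine$labels]]),
               unname(fine$matrix))
  # merging q and r sums their cells
  merged <- ifelse(labs == "p", "p", "qr")
  dm <- fragment_decompose(h, fragment_partition(merged, mol), lag = 3)
  expect_equal(dm$matrix["p", "p"], fine$matrix["p", "p"])
  expect_equal(dm$matrix["p", "qr"],
               fine$matrix["p", "q"] + fine$matrix["p", "r"])
  expect_equal(dm$matrix["qr", "qr"],
               fine$matrix["q", "q"] + fine$matrix["r", "r"] +
                 fine$matrix["q", "r"])
})

test_that("a fragment with no internal lag-5 pairs has a zero intra cell", {
  # middle CH2-CH2 of n-octane: internal distances are all < 5, so the
  # fragment cannot contribute intra-fragment terms at lag 5 (the same
  # geometry-independent mechanism that silences a compact common core)
  mol <- make_n_alkane(8)
  topo <- topological_distances(mol)
  core <- c(4:5, which(mol$elements == "H" &
                         apply(topo$dist[, 4:5, drop = FALSE] == 1, 1L, any)))
  expect_lt(max(topo$dist[core, core]), 5)
  labs <- ifelse(seq_len(n_atoms(mol)) %in% core, "core", "rest")
  dec <- fragment_decompose(hats_profile(mol, "m", 5),
                            fragment_partition(labs, mol), lag = 5)
  expect_equal(dec$matrix["core", "core"], 0)
  expect_gt(dec$matrix["core", "rest"], 0)  # inter pairs do exist
})

test_that("substructure_cut keeps coordinates and induces bonds", {
  mol <- make_n_alkane(20)
  all_cut <- substructure_cut(mol, seq_len(n_atoms(mol)))
  expect_identical(all_cut$index_map, seq_len(n_atoms(mol)))
  expect_equal(all_cut$molecule$coords, mol$coords, ignore_attr = TRUE)
  expect_identical(unname(all_cut$molecule$bonds), unname(mol$bonds))

  # keep the first 12 carbons and their hydrogens (no capping, so the cut
  # carbon keeps only its original 2 H): 37 atoms, mean leverage 3/37
  # strictly above the parent's 3/62
  topo <- topological_distances(mol)
  keep <- c(1:12, which(mol$elements == "H" &
                          apply(topo$dist[, 1:12, drop = FALSE] == 1, 1L, any)))
  cut <- substructure_cut(mol, keep)
  expect_equal(n_atoms(cut$molecule), 37L)
  mm <- molecular_influence_matrix(cut$molecule)
  expect_equal(mm$mean_leverage, 3 / 37)
  expect_gt(3 / 37, 3 / 62)
  expect_error(substructure_cut(mol, integer(0)), "empty")
  expect_error(substructure_cut(mol, 999L), "outside")
})

test_that("cutting a terminal halogen with lag-5 partners lowers HATS5m", {
  mol <- make_halide_probe("Br")
  x <- n_atoms(mol)  # substituent is the last atom
  h_full <- coef(hats_profile(mol, "m", 5))["m", "5"]
  cut <- substructure_cut(mol, setdiff(seq_len(x), x))$molecule
  h_cut <- coef(hats_profile(cut, "m", 5))["m", "5"]
  expect_lt(h_cut, h_full)
})

test_that("weighting sensitivity table is conserved and scheme-consistent", {
  mol <- make_halide_probe("Br")
  labs <- ifelse(seq_len(n_atoms(mol)) == n_atoms(mol), "R4", "core")
  part <- fragment_partition(labs, mol)
  tab <- weighting_sensitivity(mol, part, lag = 5)
  totals <- attr(tab, "totals")
  for (s in unique(tab$scheme))
    expect_equal(sum(tab$contribution[tab$scheme == s]), unname(totals[[s]]),
                 tolerance = 1e-12)
  # mass scheme inflates the Br-containing cells over unweighted
  br_cells <- tab$fragment_a == "R4" | tab$fragment_b == "R4"
  u <- tab$contribution[tab$scheme == "u" & br_cells & tab$contribution > 0]
  m <- tab$contribution[tab$scheme == "m" & br_cells & tab$contribution > 0]
  expect_true(all(m > u))
  # all-carbon molecule: u and m columns identical
  c60 <- make_fullerene_c60()
  p60 <- fragment_partition(rep(c("a", "b"), each = 30L), c60)
  t60 <- weighting_sensitivity(c60, p60, lag = 5, schemes = c("u", "m"))
  expect_equal(t60$contribution[t60$scheme == "u"],
               t60$contribution[t60$scheme == "m"])
})
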