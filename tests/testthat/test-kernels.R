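test_that("the chain-motif node kernel gates on label multisets", {
  m <- chain_molecule(4, bond_length = 1, geometry = "collinear")
  f <- cmotif_feature(m, 1:4)
  expect_equal(knc_node_kernel(f, f), sum(f$x^2))
  expect_gt(knc_node_kernel(f, f), 0)
  f_o <- f; f_o$label4 <- c("C", "C", "C", "O")
  f_n <- f; f_n$label4 <- c("C", "C", "C", "N")
  expect_equal(knc_node_kernel(f_o, f_n), 0)
  # a motif and its reversal share the multiset; value is the permuted dot
  fr <- cmotif_feature(m, 4:1)
  expect_equal(knc_node_kernel(f, fr), sum(f$x * fr$x))
  expect_gt(knc_node_kernel(f, fr), 0)
  # ordered Dirac closes the gate when the tuple order differs
  g <- chain_molecule(4, labels = c("O", "C", "C", "C"))
  fo1 <- cmotif_feature(g, 1:4); fo2 <- cmotif_feature(g, 4:1)
  expect_equal(knc_node_kernel(fo1, fo2, dirac = "ordered"), 0)
  expect_gt(knc_node_kernel(fo1, fo2, dirac = "multiset"), 0)
})

test_that("the 3D node kernel matches the hand-evaluated chain-end example", {
  m <- chain_molecule(4, bond_length = 1, geometry = "collinear")
  map <- node_feature_map(m)
  f <- cmotif_feature(m, 1:4)
  # two chain-end carbons of identical fixtures: one matching path pair
  expect_equal(kn3d_node_kernel(map, map, 1, 1), sum(f$x^2))
  # interior atoms start no 3-hop path: empty sum
  expect_equal(kn3d_node_kernel(map, map, 2, 2), 0)
  # different atom labels close the Dirac gate
  m2 <- chain_molecule(4, labels = c("N", "C", "C", "C"),
                       bond_length = 1, geometry = "collinear")
  map2 <- node_feature_map(m2)
  expect_equal(kn3d_node_kernel(map, map2, 1, 1), 0)
})

test_that("cmgk is symmetric, positive on chains, zero on disjoint alphabets", {
  m <- chain_molecule(5)
  expect_gt(cmgk(m, m), 0)
  g1 <- sample_molecule(9, seed = 41, ring_prob = 0.2)
  g2 <- sample_molecule(8, seed = 42, ring_prob = 0.2)
  expect_equal(cmgk(g1, g2), cmgk(g2, g1), tolerance = 1e-12)
  other <- sample_molecule(9, seed = 43, label_alphabet = c("S", "P"))
  expect_equal(cmgk(g1, other), 0)
  expect_equal(cmgk(star_k13(), m), 0)  # empty chain-motif graph
})

test_that("cmgk and ghk3d are invariant to rigid motions", {
  withr::local_seed(55)
  g <- sample_molecule(11, seed = 50, ring_prob = 0.15)
  kc <- cmgk(g, g); k3 <- ghk3d(g, g)
  for (i in 1:5) {
    g2 <- transform_molecule(g, random_rotation(), stats::rnorm(3, sd = 10))
    expect_lt(abs(cmgk(g, g2) - kc), 1e-8 * kc)
    expect_lt(abs(ghk3d(g, g2) - k3), 1e-8 * k3)
  }
})

test_that("mirror-image conformers give identical kernel values", {
  # distance-only featurization cannot distinguish enantiomers
  g <- sample_molecule(10, seed = 61, ring_prob = 0.2)
  mirror <- g
  mirror$coords[, 1] <- -mirror$coords[, 1]
  expect_equal(cmgk(g, mirror), cmgk(g, g), tolerance = 1e-10)
  expect_equal(ghk3d(g, mirror), ghk3d(g, g), tolerance = 1e-10)
})

test_that("ghk3d equals the literal double sum over brute-force weights", {
  withr::local_seed(66)
  for (i in 1:10) {
    g1 <- sample_molecule(sample(4:8, 1), seed = sample.int(1e6, 1),
                          ring_prob = 0.25)
    g2 <- sample_molecule(sample(4:8, 1), seed = sample.int(1e6, 1),
                          ring_prob = 0.25)
    w <- brute_force_weights(g1, g2)
    map1 <- node_feature_map(g1); map2 <- node_feature_map(g2)
    kn <- outer(seq_len(n_atoms(g1)), seq_len(n_atoms(g2)),
                Vectorize(function(v, v2) kn3d_node_kernel(map1, map2,
                                                           v, v2)))
    expect_equal(ghk3d(g1, g2), sum(w * kn), tolerance = 1e-12)
  }
})

test_that("ghk2d uses labels only and matches the brute-force value", {
  e1 <- single_edge_mol(name = "e1")
  e2 <- single_edge_mol(name = "e2")
  w <- brute_force_weights(e1, e2)
  gate <- outer(e1$labels, e2$labels, "==") * 1
  expect_equal(ghk2d(e1, e2), sum(w * gate))
  expect_equal(ghk2d(e1, e2), 8)  # four open gates, each with weight 2
  # invariant to arbitrary (non-rigid) coordinate changes
  g <- sample_molecule(9, seed = 71, ring_prob = 0.2)
  warped <- g
  warped$coords <- warped$coords^3 + 1
  expect_equal(ghk2d(g, warped), ghk2d(g, g))
  disjoint <- sample_molecule(9, seed = 72, label_alphabet = c("F", "Cl"))
  expect_equal(ghk2d(g, disjoint), 0)
})

test_that("gram matrices are symmetric PSD for all four kernels", {
  mols <- sample_molecules(8, seed = 81, size_range = c(6, 14),
                           ring_prob = 0.15)
  for (kn in c("cmgk", "3dghk", "ghk2d", "3dghk_2hop")) {
    g <- gram_matrix(mols, kernel_config(kn))
    expect_symmetric_psd(g)
  }
})

test_that("config switches are honored end to end", {
  mols <- sample_molecules(5, seed = 91, size_range = c(6, 10))
  norm <- gram_matrix(mols, kernel_config("3dghk", normalize = TRUE))
  pos <- diag(norm$values) > 0
  expect_equal(diag(norm$values)[pos], rep(1, sum(pos)),
               ignore_attr = TRUE)
  expect_symmetric_psd(norm)
  for (cfgv in list(kernel_config("cmgk", dedupe_reversed = TRUE),
                    kernel_config("cmgk", dirac = "ordered"),
                    kernel_config("3dghk", include_trivial_paths = TRUE))) {
    g <- gram_matrix(mols, cfgv)
    expect_symmetric_psd(g)
  }
  single <- gram_matrix(mols[[1]], kernel_config("ghk2d"))
  expect_equal(dim(single$values), c(1L, 1L))
  expect_equal(single$values[1, 1], ghk2d(mols[[1]], mols[[1]]))
})

test_that("gram matrices round trip through the text format", {
  mols <- sample_molecules(4, seed = 95, size_range = c(5, 8))
  g <- gram_matrix(mols, kernel_config("3dghk"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gram(g, f)
  back <- read_gram(f)
  expect_equal(back$names, g$names)
  expect_equal(back$values, g$values, tolerance = 1e-10)
  long <- tidy(g)
  expect_equal(nrow(long), 16L)
  gl <- glance(g)
  expect_equal(gl$n, 4L)
  expect_gte(gl$min_eigen, -1e-8 * gl$trace)
})
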