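test_that("k-hop path enumeration matches exhaustive expectations", {
  p4 <- chain_molecule(4)
  expect_equal(khop_paths(p4, 3),
               rbind(c(1L, 2L, 3L, 4L), c(4L, 3L, 2L, 1L)))
  expect_equal(nrow(khop_paths(star_k13(), 3)), 0L)
  c4 <- cycle_molecule(4)
  paths <- khop_paths(c4, 3)
  expect_equal(nrow(paths), 8L)           # 2 directed 3-edge paths per start
  expect_equal(as.vector(table(paths[, 1L])), rep(2L, 4L))
  # every row is a simple path along edges
  for (r in seq_len(nrow(paths))) {
    expect_equal(anyDuplicated(paths[r, ]), 0L)
  }
  # path graph on 5 nodes: interior starts have one outward direction each
  expect_equal(nrow(khop_paths(chain_molecule(5), 3)), 4L)
})

test_that("the chain adjacency mask and tensor pipeline give the closed forms", {
  m <- chain_molecule(4, bond_length = 1, geometry = "collinear")
  tens <- path_tensors(m, 1:4)
  expect_equal(tens$Adj,
               rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                     c(0, 1, 0, 1), c(0, 0, 1, 0)))
  expect_equal(tens$A2[1, 3], 1)                       # exp(-(1+1-2))
  expect_equal(tens$A3[1, 4], exp(2), tolerance = 1e-12)
  expect_equal(tens$A3[4, 1], exp(2), tolerance = 1e-12)
  # masked matrix zero pattern and excluded diagonals
  expect_true(all((tens$A1 == 0) == (tens$Adj == 0)))
  expect_equal(diag(tens$A2), rep(0, 4))
  expect_equal(diag(tens$A3), rep(0, 4))
  expect_true(all(tens$A > 0 & tens$A <= 1))
})

test_that("pipeline entries equal the printed closed forms on random paths", {
  withr::local_seed(42)
  checked <- 0L
  while (checked < 500L) {
    g <- sample_molecule(sample(6:14, 1), seed = sample.int(1e6, 1),
                         ring_prob = 0.2)
    paths <- khop_paths(g, 3)
    if (nrow(paths) == 0L) next
    take <- paths[sample.int(nrow(paths), min(10L, nrow(paths))), ,
                  drop = FALSE]
    for (r in seq_len(nrow(take))) {
      tens <- path_tensors(g, take[r, ])
      d <- tens$d
      expect_equal(tens$A2[1, 3],
                   exp(-(d[1, 2] + d[2, 3] - d[1, 3])), tolerance = 1e-10)
      expect_equal(tens$A2[2, 4],
                   exp(-(d[2, 3] + d[3, 4] - d[2, 4])), tolerance = 1e-10)
      expect_equal(tens$A3[1, 4],
                   exp(-(d[1, 2] + d[2, 3] + d[3, 4] - d[1, 3] - d[1, 4])),
                   tolerance = 1e-10)
      expect_equal(tens$A3[4, 1],
                   exp(-(d[1, 2] + d[2, 3] + d[3, 4] - d[2, 4] - d[1, 4])),
                   tolerance = 1e-10)
      checked <- checked + 1L
    }
  }
})

test_that("bond-length similarity decreases as the bond stretches", {
  short <- chain_molecule(4, bond_length = 1.2, geometry = "collinear")
  long <- chain_molecule(4, geometry = "coords",
                         coords = rbind(c(-0.3, 0, 0), short$coords[2:4, ]))
  a1s <- path_tensors(short, 1:4)$A1
  a1l <- path_tensors(long, 1:4)$A1
  expect_lt(a1l[1, 2], a1s[1, 2])
  expect_equal(a1l[2, 3], a1s[2, 3])  # untouched bonds unchanged
})

test_that("the 13-entry chain-motif feature matches the collinear worked example", {
  m <- chain_molecule(4, bond_length = 1, geometry = "collinear")
  f <- cmotif_feature(m, 1:4)
  expect_equal(f$label4, rep("C", 4))
  expect_equal(unname(f$x),
               c(exp(-1), exp(-1), exp(-1), exp(-2), exp(-2), exp(-3),
                 1, 1, 2 * exp(2)),
               tolerance = 1e-12)
  rev_ <- cmotif_feature(m, 4:1)
  expect_equal(rev_$label4, rev(f$label4))
  # reversal permutes the distance entries and swaps the angle entries
  expect_equal(unname(rev_$x[c("s_ab", "s_bc", "s_cd")]),
               unname(f$x[c("s_cd", "s_bc", "s_ab")]))
  expect_equal(unname(rev_$x[c("s_ac", "s_bd", "s_ad")]),
               unname(f$x[c("s_bd", "s_ac", "s_ad")]))
  expect_equal(unname(rev_$x["ang_ac"]), unname(f$x["ang_bd"]))
  expect_equal(unname(rev_$x["tors"]), unname(f$x["tors"]))
})

test_that("path features are invariant to rigid motions of the molecule", {
  g <- sample_molecule(12, seed = 9, ring_prob = 0.15)
  g2 <- transform_molecule(g, random_rotation(4), c(-3, 7, 2))
  paths <- khop_paths(g, 3)
  for (r in seq_len(min(20L, nrow(paths)))) {
    expect_equal(cmotif_feature(g, paths[r, ])$x,
                 cmotif_feature(g2, paths[r, ])$x, tolerance = 1e-10)
  }
})

test_that("node feature maps store each starting path under its label key", {
  p4 <- chain_molecule(4, labels = c("C", "C", "C", "O"))
  map <- node_feature_map(p4)
  expect_equal(lengths(lapply(unclass(map), `[[`, "key")),
               c(1L, 0L, 0L, 1L))
  expect_equal(map[[1]]$key, "C>C>C>O")
  expect_equal(map[[4]]$key, "O>C>C>C")
  # conservation: stored paths sum to the directed path count
  for (s in 1:5) {
    g <- sample_molecule(10, seed = s, ring_prob = 0.2)
    map <- node_feature_map(g)
    expect_equal(sum(lengths(lapply(unclass(map), `[[`, "key"))),
                 nrow(khop_paths(g, 3)))
  }
})

test_that("2-hop features reduce to three distances plus one angle similarity", {
  right <- molecule_graph(c("C", "C", "C"),
                          rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
                          rbind(1:2, 2:3), "right")
  f <- twohop_feature(right, 1:3)
  expect_equal(unname(f$x["ang_ac"]), exp(-(2 - sqrt(2))), tolerance = 1e-12)
  lin <- chain_molecule(3, bond_length = 1, geometry = "collinear")
  expect_equal(unname(twohop_feature(lin, 1:3)$x["ang_ac"]), 1)
  equi <- molecule_graph(c("C", "C", "C"),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                         rbind(1:2, 2:3), "equi")
  expect_equal(unname(twohop_feature(equi, 1:3)$x["ang_ac"]), exp(-1),
               tolerance = 1e-12)
  expect_equal(length(f$x), 4L)
  expect_equal(length(f$label3), 3L)
})

test_that("path_features returns one tidy row per directed path", {
  g <- chain_molecule(5, labels = c("C", "N", "C", "O", "C"))
  tab <- path_features(g)
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), nrow(khop_paths(g, 3)))
  expect_true(all(c("molecule", "start", "labels", "tors") %in% names(tab)))
  expect_equal(nrow(path_features(star_k13())), 0L)
})
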