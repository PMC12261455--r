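# fixtures shared across test files; everything is generated in code

# planar cis / trans quadruples used by the torsion examples
cis_quad <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
trans_quad <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))

single_edge_mol <- function(labels = c("C", "C"), name = "edge") {
  molecule_graph(labels, rbind(c(0, 0, 0), c(1.5, 0, 0)), rbind(1:2), name)
}

star_k13 <- function(name = "star") {
  molecule_graph(
    c("C", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1, 0, 0), c(-0.5, 0.87, 0), c(-0.5, -0.87, 0)),
    rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)), name)
}

cycle_molecule <- function(n, labels = "C", name = sprintf("cycle%d", n)) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1.5 / (2 * sin(pi / n))  # unit-ish bond length
  coords <- cbind(r * cos(theta), r * sin(theta), 0)
  if (length(labels) == 1L) labels <- rep(labels, n)
  i <- seq_len(n)
  molecule_graph(labels, coords, cbind(i, c(i[-1L], 1L)), name)
}

# a random non-degenerate quadruple: four Gaussian points with all pairwise
# distances in [0.5, 3] and both bonded triples clearly non-collinear
random_quadruple <- function() {
  repeat {
    p <- matrix(stats::rnorm(12), 4, 3)
    d <- as.matrix(stats::dist(p))
    dd <- d[upper.tri(d)]
    if (any(dd < 0.5) || any(dd > 3)) next
    s1 <- 1 - bond_angle_cos(d[1, 2], d[2, 3], d[1, 3])^2
    s2 <- 1 - bond_angle_cos(d[2, 3], d[3, 4], d[2, 4])^2
    if (sqrt(max(0, s1)) > 1e-3 && sqrt(max(0, s2)) > 1e-3) return(p)
  }
}

# two molecule families with disjoint atom alphabets: the cross-family
# Dirac gates are all closed, so every kernel is block-diagonal
separable_set <- function(per_family = 12, seed = 1) {
  fam_a <- sample_molecules(per_family, seed = seed,
                            size_range = c(7, 12),
                            label_alphabet = c("C", "N"))
  fam_b <- sample_molecules(per_family, seed = seed + 5000,
                            size_range = c(7, 12),
                            label_alphabet = c("S", "P"))
  mols <- c(fam_a, fam_b)
  labels <- tibble::tibble(
    name = vapply(mols, function(m) m$name, character(1)),
    label = rep(c("active", "inactive"), each = per_family))
  list(mols = mols, labels = labels)
}

# literal shared-atom edge construction for motif graphs (test oracle)
brute_motif_edges <- function(paths) {
  k <- nrow(paths)
  if (k < 2L) return(matrix(integer(0), 0L, 2L))
  hits <- vector("list", k * (k - 1L) / 2L)
  m <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (length(intersect(paths[i, ], paths[j, ])) > 0L) {
        m <- m + 1L
        hits[[m]] <- c(i, j)
      }
    }
  }
  if (m == 0L) return(matrix(integer(0), 0L, 2L))
  matrix(as.integer(unlist(hits[seq_len(m)])), ncol = 2L, byrow = TRUE)
}

expect_symmetric_psd <- function(gram, tol_factor = 1e-8) {
  v <- gram$values
  expect_lt(max(abs(v - t(v))), 1e-9 * max(1, max(abs(v))))
  expect_gte(gram_min_eigen(gram), -tol_factor * sum(diag(v)))
}
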