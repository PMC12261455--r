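#' Enumerate simple k-hop paths
#'
#' All directed simple paths with `hops` edges, enumerated from every start
#' atom. A chain A-B-C-D therefore appears twice, once per direction; this
#' matches the "T paths starting from each atom" accounting used by the 3D
#' featurization. Output rows are sorted lexicographically by atom index so
#' downstream constructions are reproducible.
#'
#' @param g a [molecule_graph()] (any object with `$labels` and `$edges`
#'   works).
#' @param hops number of edges per path (2 or 3 are used by the kernels).
#' @return integer matrix with `hops + 1` columns, one row per directed
#'   path; zero rows when the graph has none.
#' @examples
#' khop_paths(chain_molecule(4), 3) # the two directions of the chain
#' @export
khop_paths <- function(g, hops = 3L) {
  n <- length(g$labels)
  hops <- as.integer(hops)
  stopifnot(hops >= 1L)
  adj <- adjacency_list(n, g$edges)
  acc <- list()
  extend <- function(path) {
    if (length(path) == hops + 1L) {
      acc[[length(acc) + 1L]] <<- path
      return(invisible())
    }
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) extend(c(path, nb))
    }
  }
  for (s in seq_len(n)) extend(s)
  if (length(acc) == 0L) {
    return(matrix(integer(0), 0L, hops + 1L))
  }
  m <- do.call(rbind, acc)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# fixed chain adjacency of a 4-atom path A-B-C-D
chain_adjacency <- function(k = 4L) {
  adj <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    adj[i, i + 1L] <- 1
    adj[i + 1L, i] <- 1
  }
  adj
}

# elementwise division of off-diagonal entries; diagonal forced to zero
# (self-interaction carries no angle/torsion information)
odiv <- function(x, a) {
  r <- x / a
  diag(r) <- 0
  r
}

#' Path similarity tensor chain
#'
#' For a 3-hop path A-B-C-D, builds the 4x4 distance matrix `d`, the
#' distance-similarity matrix `A = exp(-d)`, the chain-masked `A1 = A * Adj`
#' (elementwise), the bond-angle matrix `A2 = (A1 %*% A1) / A` (off-diagonal
#' division, zero diagonal) and the torsion matrix
#' `A3 = (A2 %*% A1) / A` (same convention). The pipeline has closed-form
#' entries: `A2[A,C] = exp(-(d_AB + d_BC - d_AC))` encodes the bond angle at
#' B and `A3[A,D] = exp(-(d_AB + d_BC + d_CD - d_AC - d_AD))` is a linear
#' surrogate for the torsion angle, all in terms of pairwise distances only.
#'
#' @param g a [molecule_graph()].
#' @param path integer vector of 4 atom indices forming a simple path.
#' @return list with matrices `d`, `A`, `Adj`, `A1`, `A2`, `A3`.
#' @export
path_tensors <- function(g, path) {
  k <- length(path)
  p <- g$coords[path, , drop = FALSE]
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- NULL
  a <- exp(-d)
  adj <- chain_adjacency(k)
  a1 <- a * adj
  a2 <- odiv(a1 %*% a1, a)
  a3 <- odiv(a2 %*% a1, a)
  list(d = d, A = a, Adj = adj, A1 = a1, A2 = a2, A3 = a3)
}

#' 13-entry chain-motif feature
#'
#' The feature of one 4-atom chain motif: the four atom labels, the six
#' pairwise distance similarities `exp(-d)` (AB, BC, CD, AC, BD, AD), the two
#' bond-angle entries `A2[A,C]` and `A2[B,D]`, and the torsion entry
#' `A3[A,D] + A3[D,A]`. The six distance entries use the unmasked similarity
#' matrix so the non-bonded pairs AC, BD, AD contribute information as well;
#' the same nine continuous values feed both the chain-motif kernel and the
#' 3D GraphHopper node kernel.
#'
#' @param g a [molecule_graph()].
#' @param path integer vector of 4 atom indices forming a simple path.
#' @return list with `label4` (character 4-vector) and `x` (named numeric
#'   9-vector: `s_ab`, `s_bc`, `s_cd`, `s_ac`, `s_bd`, `s_ad`, `ang_ac`,
#'   `ang_bd`, `tors`).
#' @export
cmotif_feature <- function(g, path) {
  tens <- path_tensors(g, path)
  a <- tens$A
  x <- c(s_ab = a[1, 2], s_bc = a[2, 3], s_cd = a[3, 4],
         s_ac = a[1, 3], s_bd = a[2, 4], s_ad = a[1, 4],
         ang_ac = tens$A2[1, 3], ang_bd = tens$A2[2, 4],
         tors = tens$A3[1, 4] + tens$A3[4, 1])
  list(label4 = g$labels[path], x = x)
}

# feature matrix for a set of 3-hop paths; rows align with `paths` rows
cmotif_feature_matrix <- function(g, paths) {
  k <- nrow(paths)
  feats <- matrix(0, k, 9L)
  colnames(feats) <- c("s_ab", "s_bc", "s_cd", "s_ac", "s_bd", "s_ad",
                       "ang_ac", "ang_bd", "tors")
  for (i in seq_len(k)) {
    feats[i, ] <- cmotif_feature(g, paths[i, ])$x
  }
  feats
}

#' 2-hop path feature (ablation variant)
#'
#' The reduced feature used by the 2-hop ablation of the 3D GraphHopper
#' kernel: three atom labels, the three pairwise distance similarities
#' `exp(-d)` (AB, BC, AC) and one bond-angle similarity
#' `exp(-(d_AB + d_BC - d_AC))`, obtained from the 3x3 analogue of the
#' path tensor chain.
#'
#' @param g a [molecule_graph()].
#' @param path integer vector of 3 atom indices forming a simple path.
#' @return list with `label3` and `x` (named numeric 4-vector).
#' @export
twohop_feature <- function(g, path) {
  stopifnot(length(path) == 3L)
  tens <- path_tensors(g, path)
  a <- tens$A
  x <- c(s_ab = a[1, 2], s_bc = a[2, 3], s_ac = a[1, 3],
         ang_ac = tens$A2[1, 3])
  list(label3 = g$labels[path], x = x)
}

label_key <- function(labels) paste(labels, collapse = ">")

#' Per-atom k-hop path feature map
#'
#' For every atom, collects the continuous features of every directed simple
#' k-hop path starting there, grouped under the ordered atom-label tuple of
#' the path. This is the per-node representation consumed by the 3D
#' GraphHopper node kernel: two atoms match on a path pair only when the
#' ordered label tuples agree, and matching pairs contribute the linear
#' (dot-product) kernel of their features.
#'
#' @param g a [molecule_graph()].
#' @param hops 3 (default) or 2 for the ablation featurization.
#' @return object of class `node_feature_map`: a list with one entry per
#'   atom, each a list with `key` (character, one per path) and `feat`
#'   (numeric matrix, one row per path); attribute `labels` carries the atom
#'   labels.
#' @export
node_feature_map <- function(g, hops = 3L) {
  hops <- as.integer(hops)
  stopifnot(hops %in% c(2L, 3L))
  n <- length(g$labels)
  paths <- khop_paths(g, hops)
  width <- if (hops == 3L) 9L else 4L
  feats <- if (nrow(paths) == 0L) {
    matrix(0, 0L, width)
  } else if (hops == 3L) {
    cmotif_feature_matrix(g, paths)
  } else {
    t(apply(paths, 1L, function(p) twohop_feature(g, p)$x))
  }
  out <- vector("list", n)
  for (v in seq_len(n)) {
    rows <- which(paths[, 1L] == v)
    out[[v]] <- list(
      key = vapply(rows, function(r) label_key(g$labels[paths[r, ]]),
                   character(1)),
      feat = feats[rows, , drop = FALSE]
    )
  }
  structure(out, labels = g$labels, hops = hops,
            class = "node_feature_map")
}

# per-atom named list: label key -> sum of feature vectors under that key
# (valid because the path-matching kernel is linear: the double sum over
# matching path pairs factorizes into a dot product of per-key sums)
feature_key_sums <- function(map) {
  lapply(unclass(map), function(entry) {
    if (length(entry$key) == 0L) return(list())
    keys <- unique(entry$key)
    out <- lapply(keys, function(k) {
      colSums(entry$feat[entry$key == k, , drop = FALSE])
    })
    names(out) <- keys
    out
  })
}

#' Tidy table of per-path 3D features
#'
#' One row per directed k-hop path: the molecule name, the start atom, the
#' atom indices and labels along the path, and the continuous feature
#' columns. This is the tabular view of [node_feature_map()] used by the
#' command-line `features` subcommand.
#'
#' @param mols a `molecule_graph` or list of them.
#' @param hops 3 (default) or 2.
#' @return tibble.
#' @export
path_features <- function(mols, hops = 3L) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  purrr::map_dfr(mols, function(g) {
    paths <- khop_paths(g, hops)
    if (nrow(paths) == 0L) return(tibble::tibble())
    feats <- if (hops == 3L) {
      cmotif_feature_matrix(g, paths)
    } else {
      t(apply(paths, 1L, function(p) twohop_feature(g, p)$x))
    }
    lab <- apply(paths, 1L, function(p) label_key(g$labels[p]))
    tibble::tibble(
      molecule = g$name,
      start = paths[, 1L],
      path = apply(paths, 1L, paste, collapse = "-"),
      labels = lab
    ) |> dplyr::bind_cols(tibble::as_tibble(feats))
  })
}
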