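#' GraphHopper core: shortest-path position counting
#'
#' The GraphHopper kernel compares two graphs by summing a node kernel over
#' all node pairs, weighted by how often the two nodes co-occur at the same
#' position on equal-length shortest paths. The weight factorizes as
#' `w(v, v') = <M(v), M(v')>`, where the occurrence matrix `M(v)` is a
#' `delta x delta` table whose `(i, j)` entry counts the shortest paths of
#' discrete length `j` (nodes counted, so an edge has length 2) on which `v`
#' sits at position `i`. All shortest paths between every ordered node pair
#' are counted, not one representative per pair, which makes the weights
#' deterministic and tie-free. Trivial single-node paths (length 1) are
#' excluded by default; `include_trivial = TRUE` restores them.
#'
#' @name hopper
NULL

# normalize the graph argument: anything with $edges plus a node count
as_hop_graph <- function(g) {
  if (inherits(g, "molecule_graph")) {
    list(n = length(g$labels), edges = g$edges)
  } else if (inherits(g, "cmotif_graph")) {
    list(n = nrow(g$paths), edges = g$edges)
  } else if (is.list(g) && !is.null(g$n) && !is.null(g$edges)) {
    list(n = as.integer(g$n), edges = matrix(as.integer(g$edges), ncol = 2L))
  } else {
    stop("cannot interpret `g` as a graph", call. = FALSE)
  }
}

# dense shortest-path distance matrix (Inf across components) and the
# all-shortest-path count matrix, via level-wise boolean/count products
hop_distance_counts <- function(n, edges) {
  if (n == 0L) {
    return(list(D = matrix(numeric(0), 0L, 0L),
                N = matrix(numeric(0), 0L, 0L), delta = 0L))
  }
  a <- matrix(0, n, n)
  if (nrow(edges) > 0L) {
    a[edges] <- 1
    a[edges[, 2:1, drop = FALSE]] <- 1
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  done <- diag(n) > 0
  cur <- diag(n)
  k <- 0L
  repeat {
    k <- k + 1L
    cur <- (cur %*% a) > 0
    new <- cur & !done
    if (!any(new)) break
    d[new] <- k
    done <- done | new
    cur <- new * 1
  }
  nsp <- diag(n)
  ncur <- diag(n)
  maxd <- max(d[is.finite(d)])
  if (maxd >= 1) {
    for (k in seq_len(maxd)) {
      ncur <- (ncur %*% a) * (d == k)
      nsp <- nsp + ncur
    }
  }
  list(D = d, N = nsp, delta = as.integer(maxd + 1L))
}

#' Discrete diameter of a graph
#'
#' The maximal number of nodes on any shortest path (so a single edge has
#' diameter 2, an isolated node 1). For disconnected graphs the maximum is
#' taken per connected component.
#'
#' @param g a [molecule_graph()], [cmotif_graph()], or list with `n` and
#'   `edges`.
#' @return integer diameter (0 for the empty graph).
#' @export
graph_diameter <- function(g) {
  hg <- as_hop_graph(g)
  hop_distance_counts(hg$n, hg$edges)$delta
}

# occurrence matrices flattened to an n x delta^2 matrix (column-major in
# (position i, length j)); built from the identity that a node v lies at
# position i of a shortest s->w path of length j iff dist(s,v) = i-1,
# dist(v,w) = j-i and dist(s,w) = j-1, in which case the number of such
# paths is N[s,v] * N[v,w]
occurrence_flat <- function(n, edges, delta = NULL, include_trivial = FALSE) {
  dc <- hop_distance_counts(n, edges)
  own <- max(dc$delta, 1L)
  if (is.null(delta)) delta <- own
  delta <- as.integer(delta)
  if (n > 0L && delta < dc$delta) {
    stop(sprintf("delta = %d is smaller than the graph diameter %d",
                 delta, dc$delta), call. = FALSE)
  }
  flat <- matrix(0, n, delta * delta)
  if (n == 0L) return(structure(flat, delta = delta))
  d <- dc$D; nsp <- dc$N
  for (i in seq_len(dc$delta)) {
    ai <- nsp * (d == (i - 1L))
    for (r in 0:(dc$delta - i)) {
      j <- i + r
      if (j == 1L && !include_trivial) next
      ar <- nsp * (d == r)
      cj <- (d == (j - 1L)) * 1
      flat[, (j - 1L) * delta + i] <- rowSums((t(ai) %*% cj) * ar)
    }
  }
  structure(flat, delta = delta)
}

#' Occurrence matrices of all nodes
#'
#' Computes the `delta x delta` occurrence matrix `M(v)` for every node:
#' entry `(i, j)` is the number of shortest paths of discrete length `j` on
#' which `v` appears at position `i`, counted over all ordered node pairs
#' and all tied shortest paths. Matrices are zero-padded to `delta`, which
#' must be at least the graph's own diameter; padding never changes inner
#' products of occurrence matrices.
#'
#' @param g a [molecule_graph()], [cmotif_graph()], or list with `n`,
#'   `edges`.
#' @param delta padding dimension; defaults to the graph diameter.
#' @param include_trivial also count single-node paths (adds 1 at entry
#'   `(1, 1)` of every node's matrix).
#' @return list of `delta x delta` numeric matrices, one per node.
#' @examples
#' occurrence_matrices(chain_molecule(3))[[2]] # center atom of a 3-chain
#' @export
occurrence_matrices <- function(g, delta = NULL, include_trivial = FALSE) {
  hg <- as_hop_graph(g)
  flat <- occurrence_flat(hg$n, hg$edges, delta, include_trivial)
  delta <- attr(flat, "delta")
  lapply(seq_len(hg$n), function(v) {
    matrix(flat[v, ], delta, delta)
  })
}

#' GraphHopper weight table of a graph pair
#'
#' `w(v, v') = <M(v), M(v')>`, the Frobenius inner product of the two
#' occurrence matrices padded to the larger of the two diameters. Nodes in
#' small or disconnected components simply contribute zero rows.
#'
#' @param g,g2 graphs (see [occurrence_matrices()] for accepted types).
#' @param include_trivial count single-node paths in both graphs.
#' @return numeric matrix with one row per node of `g` and one column per
#'   node of `g2`.
#' @export
hop_weights <- function(g, g2, include_trivial = FALSE) {
  h1 <- as_hop_graph(g)
  h2 <- as_hop_graph(g2)
  f1 <- occurrence_flat(h1$n, h1$edges, include_trivial = include_trivial)
  f2 <- occurrence_flat(h2$n, h2$edges, include_trivial = include_trivial)
  cross_weights(f1, f2)
}

# inner products of flattened occurrence matrices with different paddings:
# only the common top-left block can be jointly nonzero
cross_weights <- function(f1, f2) {
  d1 <- attr(f1, "delta"); d2 <- attr(f2, "delta")
  d <- min(d1, d2)
  if (d == 0L || nrow(f1) == 0L || nrow(f2) == 0L) {
    return(matrix(0, nrow(f1), nrow(f2)))
  }
  idx <- function(dd) as.vector(outer(seq_len(d), seq_len(d),
                                      function(i, j) (j - 1L) * dd + i))
  f1[, idx(d1), drop = FALSE] %*% t(f2[, idx(d2), drop = FALSE])
}

#' Brute-force GraphHopper weights (oracle)
#'
#' Literal evaluation of the weight definition: every shortest path in each
#' graph is enumerated explicitly (all simple paths between each ordered
#' pair, filtered to minimal length), occurrence matrices are filled by
#' walking each path position by position, and weights are their inner
#' products. Exponential in the worst case, so graphs are capped at 10
#' nodes; exists as an independent cross-check of [hop_weights()].
#'
#' @inheritParams hop_weights
#' @return numeric weight matrix.
#' @export
brute_force_weights <- function(g, g2, include_trivial = FALSE) {
  h1 <- as_hop_graph(g)
  h2 <- as_hop_graph(g2)
  if (h1$n > 10L || h2$n > 10L) {
    stop("brute-force enumeration is limited to graphs with <= 10 nodes",
         call. = FALSE)
  }
  occ <- function(h) {
    if (h$n == 0L) return(structure(matrix(0, 0L, 0L), delta = 0L))
    ig <- igraph::make_empty_graph(h$n, directed = FALSE)
    if (nrow(h$edges) > 0L) {
      ig <- igraph::add_edges(ig, t(h$edges))
    }
    paths <- list()
    for (u in seq_len(h$n)) {
      for (w in seq_len(h$n)) {
        if (u == w) {
          if (include_trivial) paths[[length(paths) + 1L]] <- u
          next
        }
        sp <- igraph::all_simple_paths(ig, from = u, to = w)
        if (length(sp) == 0L) next
        lens <- vapply(sp, length, integer(1))
        for (p in sp[lens == min(lens)]) {
          paths[[length(paths) + 1L]] <- as.integer(p)
        }
      }
    }
    delta <- if (length(paths) == 0L) 1L else max(vapply(paths, length,
                                                         integer(1)))
    m <- matrix(0, h$n, delta * delta)
    for (p in paths) {
      j <- length(p)
      for (i in seq_len(j)) {
        col <- (j - 1L) * delta + i
        m[p[i], col] <- m[p[i], col] + 1
      }
    }
    structure(m, delta = delta)
  }
  cross_weights(occ(h1), occ(h2))
}

#' Weighted node-kernel sum
#'
#' The generic GraphHopper assembly `sum_v sum_v' w(v, v') k_n(v, v')`.
#'
#' @param w weight matrix from [hop_weights()].
#' @param node_kernel either a matrix conformable with `w`, or a function
#'   `f(i, j)` returning the node-kernel value for node `i` of the first
#'   graph and node `j` of the second.
#' @return scalar kernel value.
#' @export
weighted_kernel_sum <- function(w, node_kernel) {
  if (is.function(node_kernel)) {
    kn <- outer(seq_len(nrow(w)), seq_len(ncol(w)),
                Vectorize(node_kernel))
  } else {
    kn <- node_kernel
    stopifnot(all(dim(kn) == dim(w)))
  }
  sum(w * kn)
}
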