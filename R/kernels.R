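#' Kernel configuration
#'
#' Collects the switches shared by all four graph kernels.
#'
#' * `kernel`: `"3dghk"` (3D GraphHopper kernel, the default), `"cmgk"`
#'   (chain-motif graph kernel), `"ghk2d"` (label-only 2D GraphHopper
#'   baseline) or `"3dghk_2hop"` (2-hop ablation featurization).
#' * `normalize`: cosine-normalize Gram matrices
#'   (`K(i,j)/sqrt(K(i,i)K(j,j))`, 0/0 mapped to 0). Off by default;
#'   unnormalized values grow with molecule size.
#' * `include_trivial_paths`: count single-node shortest paths in the
#'   GraphHopper weights (off by default; a zero-hop path carries no hop
#'   structure).
#' * `dedupe_reversed`: collapse each chain motif with its reversal when
#'   building chain-motif graphs.
#' * `dirac`: for the chain-motif node kernel, compare motif label
#'   `"multiset"`s (default) or `"ordered"` tuples.
#' * `hydrogens`: `"strip"` (default) or `"keep"`; applied when assembling a
#'   Gram matrix.
#'
#' @param kernel,normalize,include_trivial_paths,dedupe_reversed,dirac,hydrogens
#'   see above.
#' @return object of class `kernel_config`.
#' @export
kernel_config <- function(kernel = c("3dghk", "cmgk", "ghk2d", "3dghk_2hop"),
                          normalize = FALSE,
                          include_trivial_paths = FALSE,
                          dedupe_reversed = FALSE,
                          dirac = c("multiset", "ordered"),
                          hydrogens = c("strip", "keep")) {
  structure(
    list(kernel = match.arg(kernel),
         normalize = isTRUE(normalize),
         include_trivial_paths = isTRUE(include_trivial_paths),
         dedupe_reversed = isTRUE(dedupe_reversed),
         dirac = match.arg(dirac),
         hydrogens = match.arg(hydrogens)),
    class = "kernel_config")
}

#' @export
print.kernel_config <- function(x, ...) {
  cat(sprintf(
    "<kernel_config> %s (normalize=%s, trivial_paths=%s, dedupe=%s, dirac=%s, hydrogens=%s)\n",
    x$kernel, x$normalize, x$include_trivial_paths, x$dedupe_reversed,
    x$dirac, x$hydrogens))
  invisible(x)
}

#' Chain-motif node kernel
#'
#' Node kernel between two chain motifs: a Dirac gate on the atom-label
#' multisets (1 iff the two motifs contain the same four element symbols,
#' counted with multiplicity) times the linear kernel (dot product) of the
#' nine continuous features. With `dirac = "ordered"` the gate compares the
#' label tuples in path order instead.
#'
#' @param m1,m2 motif features as returned by [cmotif_feature()].
#' @param dirac `"multiset"` (default) or `"ordered"`.
#' @return nonnegative scalar.
#' @export
knc_node_kernel <- function(m1, m2, dirac = c("multiset", "ordered")) {
  dirac <- match.arg(dirac)
  gate <- if (dirac == "multiset") {
    identical(sort(m1$label4), sort(m2$label4))
  } else {
    identical(m1$label4, m2$label4)
  }
  if (!gate) return(0)
  sum(m1$x * m2$x)
}

#' 3D node kernel of the 3D GraphHopper kernel
#'
#' For atoms `v` of one molecule and `v2` of another: a Dirac gate on the
#' two atom labels, times the sum over all pairs of k-hop paths (one
#' starting at each atom) whose ordered label tuples agree of the dot
#' product of their continuous features. An atom with no k-hop path
#' contributes an empty sum, hence 0.
#'
#' @param map,map2 feature maps from [node_feature_map()].
#' @param v,v2 atom indices into `map` and `map2`.
#' @return nonnegative scalar.
#' @export
kn3d_node_kernel <- function(map, map2, v, v2) {
  if (attr(map, "labels")[v] != attr(map2, "labels")[v2]) return(0)
  e1 <- map[[v]]; e2 <- map2[[v2]]
  if (length(e1$key) == 0L || length(e2$key) == 0L) return(0)
  shared <- intersect(unique(e1$key), unique(e2$key))
  total <- 0
  for (k in shared) {
    f1 <- e1$feat[e1$key == k, , drop = FALSE]
    f2 <- e2$feat[e2$key == k, , drop = FALSE]
    total <- total + sum(colSums(f1) * colSums(f2))
  }
  total
}

# ---- per-molecule precomputation & pair evaluation -------------------------

# everything a kernel evaluation needs from one molecule, computed once
kernel_precompute <- function(g, cfg) {
  if (cfg$hydrogens == "strip") g <- strip_hydrogens(g)
  trivial <- cfg$include_trivial_paths
  switch(cfg$kernel,
    ghk2d = {
      list(flat = occurrence_flat(n_atoms(g), g$edges,
                                  include_trivial = trivial),
           labels = g$labels)
    },
    `3dghk` = {
      map <- node_feature_map(g, 3L)
      list(flat = occurrence_flat(n_atoms(g), g$edges,
                                  include_trivial = trivial),
           labels = g$labels, sums = feature_key_sums(map))
    },
    `3dghk_2hop` = {
      map <- node_feature_map(g, 2L)
      list(flat = occurrence_flat(n_atoms(g), g$edges,
                                  include_trivial = trivial),
           labels = g$labels, sums = feature_key_sums(map))
    },
    cmgk = {
      cg <- cmotif_graph(g, dedupe_reversed = cfg$dedupe_reversed)
      keys <- if (cfg$dirac == "multiset") cg$key_multiset else cg$key_ordered
      list(flat = occurrence_flat(nrow(cg$paths), cg$edges,
                                  include_trivial = trivial),
           keys = keys, features = cg$features)
    })
}

# kernel value from two precomputed molecules
kernel_pair <- function(p1, p2, cfg) {
  w <- cross_weights(p1$flat, p2$flat)
  if (length(w) == 0L) return(0)
  kn <- switch(cfg$kernel,
    ghk2d = outer(p1$labels, p2$labels, "==") * 1,
    cmgk = {
      outer(p1$keys, p2$keys, "==") * (p1$features %*% t(p2$features))
    },
    {
      # 3dghk and its 2-hop ablation: Dirac on atom labels x linear kernel
      # over label-matched path pairs, via per-key feature sums
      kn <- outer(p1$labels, p2$labels, "==") * 1
      hits <- which(kn > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        s1 <- p1$sums[[hits[r, 1L]]]
        s2 <- p2$sums[[hits[r, 2L]]]
        val <- 0
        if (length(s1) > 0L && length(s2) > 0L) {
          for (k in intersect(names(s1), names(s2))) {
            val <- val + sum(s1[[k]] * s2[[k]])
          }
        }
        kn[hits[r, 1L], hits[r, 2L]] <- val
      }
      kn
    })
  sum(w * kn)
}

#' Evaluate one graph kernel on a molecule pair
#'
#' `mol_kernel()` dispatches on `cfg$kernel`; `cmgk()`, `ghk3d()`,
#' `ghk2d()` and `ghk3d_2hop()` are fixed-kernel shorthands. For Gram
#' matrices over many molecules use [gram_matrix()], which reuses
#' per-molecule precomputations.
#'
#' * `cmgk`: GraphHopper kernel on the two chain-motif graphs with the
#'   motif node kernel of [knc_node_kernel()]; 0 when either motif graph is
#'   empty.
#' * `ghk3d`: GraphHopper weights on the original molecular graphs against
#'   the 3-hop node kernel of [kn3d_node_kernel()].
#' * `ghk2d`: label-Dirac node kernel only; uses no coordinates.
#' * `ghk3d_2hop`: `ghk3d` with the reduced 2-hop featurization.
#'
#' @param g1,g2 [molecule_graph()] objects.
#' @param cfg a [kernel_config()]; for the shorthands only the flags are
#'   used, the kernel name is forced.
#' @return scalar kernel value.
#' @examples
#' m <- chain_molecule(5)
#' ghk3d(m, m) > 0
#' @export
mol_kernel <- function(g1, g2, cfg = kernel_config()) {
  kernel_pair(kernel_precompute(g1, cfg), kernel_precompute(g2, cfg), cfg)
}

#' @rdname mol_kernel
#' @export
cmgk <- function(g1, g2, cfg = kernel_config("cmgk")) {
  cfg$kernel <- "cmgk"
  mol_kernel(g1, g2, cfg)
}

#' @rdname mol_kernel
#' @export
ghk3d <- function(g1, g2, cfg = kernel_config("3dghk")) {
  cfg$kernel <- "3dghk"
  mol_kernel(g1, g2, cfg)
}

#' @rdname mol_kernel
#' @export
ghk2d <- function(g1, g2, cfg = kernel_config("ghk2d")) {
  cfg$kernel <- "ghk2d"
  mol_kernel(g1, g2, cfg)
}

#' @rdname mol_kernel
#' @export
ghk3d_2hop <- function(g1, g2, cfg = kernel_config("3dghk_2hop")) {
  cfg$kernel <- "3dghk_2hop"
  mol_kernel(g1, g2, cfg)
}
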