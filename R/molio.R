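#' Labeled 3D molecular graph
#'
#' The basic container used throughout the package: an undirected graph whose
#' nodes are atoms (element symbol labels), whose edges are bonds, and whose
#' nodes carry 3D coordinates in Angstrom. Bond orders, charges and
#' stereochemistry flags are deliberately not stored: every kernel in this
#' package uses only labels, adjacency and inter-atomic distances.
#'
#' @param labels character vector of atom element symbols, one per atom.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom). All values must be finite.
#' @param edges two-column integer matrix of bonds (1-based atom indices).
#'   Self-loops and duplicate bonds are rejected.
#' @param name record identifier.
#'
#' @return An object of class `molecule_graph` with fields `name`, `labels`,
#'   `coords`, `edges`.
#' @examples
#' m <- molecule_graph(c("C", "O"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
#'                     rbind(c(1L, 2L)), name = "co")
#' n_atoms(m)
#' @export
molecule_graph <- function(labels, coords, edges = NULL, name = "molecule") {
  labels <- as.character(labels)
  n <- length(labels)
  coords <- as.matrix(coords)
  if (n == 0L) {
    coords <- matrix(numeric(0), 0L, 3L)
  }
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop("`coords` must be an n x 3 matrix matching `labels`", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  if (n > 0L && !all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) {
      stop("edge endpoints out of range", call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    edges <- t(apply(edges, 1L, sort))
    edges <- matrix(as.integer(edges), ncol = 2L)
    key <- paste(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key)) {
      stop("duplicate bonds are not allowed", call. = FALSE)
    }
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(name = as.character(name)[1L], labels = labels,
         coords = coords, edges = edges),
    class = "molecule_graph"
  )
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %s: %d atoms (%s), %d bonds\n",
              x$name, n_atoms(x),
              paste(utils::head(unique(x$labels), 6L), collapse = ","),
              n_bonds(x)))
  invisible(x)
}

#' Atom and bond counts
#'
#' @param g a [molecule_graph()].
#' @return integer count.
#' @export
n_atoms <- function(g) length(g$labels)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) nrow(g$edges)

# adjacency list: integer vector of neighbors per node
adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, sort)
}

#' Read molecules from an SDF/MOL V2000 file
#'
#' Each record becomes one [molecule_graph()] in file order. Bonds are read as
#' unlabeled undirected edges; bond orders and charge annotations are
#' discarded. With `hydrogens = "strip"` (the default, the usual convention
#' for molecular graph kernels) hydrogen atoms and their incident bonds are
#' removed and atom indices are compacted. Records whose coordinate block has
#' an all-zero z column (a hallmark of 2D-only SDF output) are kept but
#' reported with a warning, since distance-based 3D features computed from
#' them are not meaningful.
#'
#' @param path path to an SDF or MOL file.
#' @param hydrogens `"strip"` (default) or `"keep"`.
#' @return list of `molecule_graph` objects; empty list for an empty file.
#'   Records that fail to parse raise an error naming the record index.
#' @export
read_sdf <- function(path, hydrogens = c("strip", "keep")) {
  hydrogens <- match.arg(hydrogens)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) NULL
  )
  if (is.null(sdfset)) {
    stop("failed to parse SDF file: ", path, call. = FALSE)
  }
  out <- vector("list", length(sdfset))
  flat <- integer(0)
  seen <- character(0)
  for (k in seq_along(sdfset)) {
    rec <- tryCatch(
      sdf_record_to_graph(sdfset[[k]]),
      error = function(e) {
        stop(sprintf("record %d: %s", k, conditionMessage(e)), call. = FALSE)
      }
    )
    if (n_atoms(rec) >= 2L && all(rec$coords[, "z"] == 0)) flat <- c(flat, k)
    if (hydrogens == "strip") rec <- strip_hydrogens(rec)
    # disambiguate duplicate record names with the record index
    if (rec$name %in% seen) rec$name <- sprintf("%s_%d", rec$name, k)
    seen <- c(seen, rec$name)
    out[[k]] <- rec
  }
  if (length(flat) > 0L) {
    warning(sprintf(
      "record(s) %s have an all-zero z column (likely 2D coordinates)",
      paste(flat, collapse = ", ")), call. = FALSE)
  }
  out
}

sdf_record_to_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) stop("empty atom block")
  coords <- ab[, 1:3, drop = FALSE]
  if (!all(is.finite(coords))) stop("non-finite coordinates in atom block")
  labels <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  edges <- NULL
  if (!is.null(bb) && nrow(bb) > 0L) {
    edges <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > nrow(ab))) {
      stop("malformed bond block")
    }
  }
  nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
  if (is.null(nm) || is.na(nm) || !nzchar(trimws(nm))) nm <- "unnamed"
  molecule_graph(labels, coords, edges, name = trimws(nm))
}

#' Remove hydrogen atoms from a molecule
#'
#' Drops all atoms labeled `"H"` together with their incident bonds and
#' compacts the remaining atom indices.
#'
#' @param g a [molecule_graph()].
#' @return the heavy-atom `molecule_graph`.
#' @export
strip_hydrogens <- function(g) {
  keep <- which(g$labels != "H")
  if (length(keep) == n_atoms(g)) return(g)
  remap <- integer(n_atoms(g))
  remap[keep] <- seq_along(keep)
  e <- g$edges
  if (nrow(e) > 0L) {
    ok <- g$labels[e[, 1L]] != "H" & g$labels[e[, 2L]] != "H"
    e <- cbind(remap[e[ok, 1L]], remap[e[ok, 2L]])
  }
  molecule_graph(g$labels[keep], g$coords[keep, , drop = FALSE], e,
                 name = g$name)
}

#' Write molecules to an SDF (MOL V2000) file
#'
#' Coordinates are written with the standard fixed-width 4-decimal atom block
#' (columns 1-30 for x, y, z; element symbol from column 32), so a write/read
#' round trip preserves coordinates to 1e-4 Angstrom. All bonds are written
#' as single bonds: bond order is not part of the in-memory model.
#'
#' @param mols a `molecule_graph` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in mols) {
    writeLines(c(
      g$name, "  mol3dkern", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              n_atoms(g), n_bonds(g))), con)
    for (i in seq_len(n_atoms(g))) {
      writeLines(sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        g$coords[i, 1L], g$coords[i, 2L], g$coords[i, 3L], g$labels[i]), con)
    }
    if (n_bonds(g) > 0L) {
      for (r in seq_len(n_bonds(g))) {
        writeLines(sprintf("%3d%3d  1  0", g$edges[r, 1L], g$edges[r, 2L]),
                   con)
      }
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read an activity label file
#'
#' Two-column tab-delimited text mapping molecule name to class
#' (`active` / `inactive`), the format used by the screening harness.
#'
#' @param path path to the label file.
#' @return tibble with columns `name` and `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "label"),
                          colClasses = "character", strip.white = TRUE)
  bad <- setdiff(unique(df$label), c("active", "inactive"))
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate molecule names in label file", call. = FALSE)
  }
  tibble::tibble(name = df$name, label = df$label)
}

#' Deterministic chain molecule
#'
#' Builds a path molecule A-B-C-... with controlled geometry. `"collinear"`
#' places atoms on the x axis at `bond_length` spacing, `"zigzag"` uses a
#' planar zigzag with tetrahedral (109.47 degree) bond angles, and
#' `"coords"` takes coordinates verbatim. Useful as a worked-example input
#' for the distance-geometry and path-feature operations.
#'
#' @param n_atoms number of atoms (>= 2).
#' @param bond_length bond length in Angstrom (ignored for `"coords"`).
#' @param labels atom labels, recycled if length 1; default all carbon.
#' @param geometry `"collinear"`, `"zigzag"` or `"coords"`.
#' @param coords explicit n x 3 matrix when `geometry = "coords"`.
#' @param name record name.
#' @return a [molecule_graph()] path graph with `n_atoms - 1` bonds.
#' @examples
#' chain_molecule(4, geometry = "collinear")
#' @export
chain_molecule <- function(n_atoms, bond_length = 1.5, labels = "C",
                           geometry = c("zigzag", "collinear", "coords"),
                           coords = NULL, name = "chain") {
  geometry <- match.arg(geometry)
  if (n_atoms < 2L) stop("`n_atoms` must be >= 2", call. = FALSE)
  if (length(labels) == 1L) labels <- rep(labels, n_atoms)
  if (length(labels) != n_atoms) {
    stop("`labels` must have length 1 or `n_atoms`", call. = FALSE)
  }
  if (geometry == "coords") {
    if (is.null(coords)) stop("`coords` required for geometry = \"coords\"",
                              call. = FALSE)
    coords <- as.matrix(coords)
    if (nrow(coords) != n_atoms) stop("`coords` must have `n_atoms` rows",
                                      call. = FALSE)
  } else if (geometry == "collinear") {
    coords <- cbind((seq_len(n_atoms) - 1) * bond_length, 0, 0)
  } else {
    # planar zigzag with tetrahedral bond angles (cosine -1/3)
    cstep <- bond_length * sqrt(2 / 3)
    h <- bond_length / sqrt(3)
    coords <- cbind((seq_len(n_atoms) - 1) * cstep,
                    (seq_len(n_atoms) %% 2L) * h, 0)
  }
  i <- seq_len(n_atoms - 1L)
  molecule_graph(labels, coords, cbind(i, i + 1L), name = name)
}

#' Random synthetic 3D molecule
#'
#' Generates a connected molecular graph as a random spanning tree (each new
#' atom attaches to a uniformly chosen earlier atom) plus ring-closing edges
#' added independently with probability `ring_prob` per non-tree atom pair.
#' Each new atom is placed at `bond_length` Angstrom from its tree parent in
#' a uniformly random direction, so bond lengths are realistic while bond
#' angles and torsions vary freely. Deterministic given `seed`; the global
#' RNG state is left untouched.
#'
#' @param n_atoms number of atoms (>= 1).
#' @param seed integer seed.
#' @param ring_prob probability of adding each candidate ring-closing edge.
#' @param label_alphabet symbols to draw atom labels from; repeats raise a
#'   symbol's frequency.
#' @param bond_length tree-edge bond length in Angstrom.
#' @param name record name; defaults to an identifier derived from the seed.
#' @return a connected [molecule_graph()].
#' @examples
#' sample_molecule(10, seed = 7)
#' @export
sample_molecule <- function(n_atoms, seed, ring_prob = 0.02,
                            label_alphabet = c("C", "C", "C", "C", "N", "O"),
                            bond_length = 1.5, name = NULL) {
  if (n_atoms < 1L) stop("`n_atoms` must be >= 1", call. = FALSE)
  if (is.null(name)) name <- sprintf("synth_%d", as.integer(seed))
  withr::with_seed(as.integer(seed), {
    labels <- sample(label_alphabet, n_atoms, replace = TRUE)
    coords <- matrix(0, n_atoms, 3L)
    edges <- NULL
    if (n_atoms > 1L) {
      parent <- c(NA_integer_,
                  vapply(2:n_atoms,
                         function(i) sample.int(i - 1L, 1L), integer(1)))
      for (i in 2:n_atoms) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        coords[i, ] <- coords[parent[i], ] + bond_length * u
      }
      edges <- cbind(parent[-1L], 2:n_atoms)
      if (ring_prob > 0 && n_atoms > 2L) {
        cand <- t(combn(n_atoms, 2L))
        tree_key <- paste(pmin(edges[, 1L], edges[, 2L]),
                          pmax(edges[, 1L], edges[, 2L]))
        cand <- cand[!(paste(cand[, 1L], cand[, 2L]) %in% tree_key), ,
                     drop = FALSE]
        add <- runif(nrow(cand)) < ring_prob
        if (any(add)) edges <- rbind(edges, cand[add, , drop = FALSE])
      }
    }
    molecule_graph(labels, coords, edges, name = name)
  })
}

#' Corpus of random synthetic molecules
#'
#' Convenience wrapper drawing `n` molecules with sizes sampled uniformly in
#' `size_range`, seeding each molecule from `seed` so the corpus is
#' reproducible as a whole.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @param size_range integer vector `c(min, max)` of atom counts.
#' @param ... passed on to [sample_molecule()].
#' @return list of [molecule_graph()] objects.
#' @export
sample_molecules <- function(n, seed, size_range = c(8L, 25L), ...) {
  sizes <- withr::with_seed(as.integer(seed), {
    sample(seq(size_range[1L], size_range[2L]), n, replace = TRUE)
  })
  lapply(seq_len(n), function(i) {
    sample_molecule(sizes[i], seed = as.integer(seed) + i,
                    name = sprintf("synth_%d_%d", as.integer(seed), i), ...)
  })
}

#' Apply a rigid motion to a molecule
#'
#' Rotates the coordinates by an orthogonal matrix and translates them; used
#' to exercise the rotation/translation invariance of the 3D kernels.
#'
#' @param g a [molecule_graph()].
#' @param rotation 3 x 3 orthogonal matrix (default identity).
#' @param translation length-3 numeric vector (default zero).
#' @return the transformed `molecule_graph`.
#' @export
transform_molecule <- function(g, rotation = diag(3), translation = c(0, 0, 0)) {
  g$coords <- g$coords %*% t(rotation) +
    matrix(translation, n_atoms(g), 3L, byrow = TRUE)
  g
}

#' Random rotation matrix
#'
#' Draws a uniformly distributed rotation (via QR of a Gaussian matrix, sign
#' fixed so the determinant is +1).
#'
#' @param seed optional integer seed.
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(rnorm(9), 3L, 3L))
    q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    q
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
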