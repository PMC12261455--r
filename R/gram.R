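#' Gram matrix over a molecule set
#'
#' Computes the `N x N` matrix of pairwise kernel values for one of the four
#' kernels, evaluating each unordered pair once (N(N+1)/2 kernel
#' evaluations) and reusing per-molecule precomputations (feature maps,
#' chain-motif graphs, occurrence matrices). With `cfg$normalize = TRUE`
#' the cosine normalization `K(i,j)/sqrt(K(i,i) K(j,j))` is applied, with
#' 0/0 mapped to 0, giving a unit diagonal wherever `K(i,i) > 0`.
#'
#' Every kernel here is a sum of `w(v,v') * (Dirac x linear)` terms with
#' `w(v,v')` itself an inner product, so the result is a valid positive
#' semidefinite kernel; [gram_min_eigen()] exposes the numerical check.
#'
#' @param mols list of [molecule_graph()] objects (length >= 1). Duplicate
#'   names are rejected.
#' @param cfg a [kernel_config()].
#' @return object of class `gram_matrix`: list with `values` (symmetric
#'   numeric matrix with molecule names as dimnames), `names`, `config`.
#'   Any non-finite kernel value aborts, naming the offending pair.
#' @examples
#' mols <- sample_molecules(4, seed = 1, size_range = c(6, 9))
#' gram_matrix(mols, kernel_config("ghk2d"))
#' @export
gram_matrix <- function(mols, cfg = kernel_config()) {
  if (inherits(mols, "molecule_graph")) mols <- list(mols)
  n <- length(mols)
  stopifnot(n >= 1L)
  nms <- vapply(mols, function(m) m$name, character(1))
  if (anyDuplicated(nms)) {
    stop("molecule names must be unique", call. = FALSE)
  }
  pre <- lapply(mols, kernel_precompute, cfg = cfg)
  k <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- kernel_pair(pre[[i]], pre[[j]], cfg)
      if (!is.finite(v)) {
        stop(sprintf("non-finite kernel value for pair (%s, %s)",
                     nms[i], nms[j]), call. = FALSE)
      }
      k[i, j] <- v
      k[j, i] <- v
    }
  }
  if (cfg$normalize) k <- cosine_normalize(k)
  structure(list(values = k, names = nms, config = cfg),
            class = "gram_matrix")
}

cosine_normalize <- function(k) {
  d <- sqrt(diag(k))
  scale <- outer(d, d)
  out <- ifelse(scale > 0, k / scale, 0)
  dimnames(out) <- dimnames(k)
  out
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix> %s kernel, %d molecules%s\n",
              x$config$kernel, length(x$names),
              if (x$config$normalize) " (cosine-normalized)" else ""))
  invisible(x)
}

#' Smallest eigenvalue of a Gram matrix
#'
#' A Gram matrix of a valid kernel is positive semidefinite up to floating
#' point: its smallest eigenvalue should not fall below about
#' `-1e-8 * trace`. Returned as-is so callers choose the tolerance.
#'
#' @param gram a [gram_matrix()].
#' @return smallest eigenvalue of the symmetrized matrix.
#' @export
gram_min_eigen <- function(gram) {
  v <- (gram$values + t(gram$values)) / 2
  min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
}

#' Tidy a Gram matrix into long form
#'
#' @param x a [gram_matrix()].
#' @param ... unused.
#' @return tibble with columns `mol1`, `mol2`, `value`.
#' @export
tidy.gram_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    mol1 = rep(rownames(v), times = ncol(v)),
    mol2 = rep(colnames(v), each = nrow(v)),
    value = as.vector(v)
  )
}

#' One-row summary of a Gram matrix
#'
#' @param x a [gram_matrix()].
#' @param ... unused.
#' @return tibble with the kernel name, dimension, trace, minimum
#'   eigenvalue and symmetry error.
#' @export
glance.gram_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    kernel = x$config$kernel,
    n = nrow(v),
    trace = sum(diag(v)),
    min_eigen = gram_min_eigen(x),
    max_asym = max(abs(v - t(v)))
  )
}

#' Heatmap of a Gram matrix
#'
#' @param object a [gram_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gram_matrix <- function(object, ...) {
  df <- tidy(object)
  df$mol1 <- factor(df$mol1, levels = object$names)
  df$mol2 <- factor(df$mol2, levels = rev(object$names))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mol1, y = .data$mol2,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "K") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s Gram matrix", object$config$kernel)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write / read a Gram matrix as tab-delimited text
#'
#' First row and first column carry the molecule names; values are written
#' with 12 significant digits.
#'
#' @param gram a [gram_matrix()].
#' @param path file path.
#' @return `write_gram` returns `path` invisibly; `read_gram` returns a
#'   `gram_matrix` (with a default config recording only the file origin).
#' @export
write_gram <- function(gram, path) {
  v <- gram$values
  header <- paste(c("name", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i],
            formatC(v[i, ], digits = 12, format = "g")), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_gram
#' @export
read_gram <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  v <- as.matrix(df)
  structure(list(values = v, names = rownames(v),
                 config = kernel_config()),
            class = "gram_matrix")
}
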