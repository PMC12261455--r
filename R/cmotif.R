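#' Chain-motif graph of a molecule
#'
#' Builds the graph whose nodes are the directed 3-hop paths (chain motifs)
#' of a molecule and whose edges join two motifs whenever they share at least
#' one atom. Each motif node carries the 13-entry feature of
#' [cmotif_feature()] (4 labels + 9 continuous values). The chain-motif
#' kernel is a GraphHopper kernel evaluated on this derived graph.
#'
#' Both directions of every chain are kept by default so that the motif
#' count matches the per-start-atom path accounting; `dedupe_reversed = TRUE`
#' keeps only the lexicographically smaller direction.
#'
#' @param g a [molecule_graph()].
#' @param dedupe_reversed drop the reversed duplicate of each chain.
#' @return object of class `cmotif_graph`: list with `source` (molecule
#'   name), `paths` (k x 4 integer matrix, lexicographic order), `features`
#'   (k x 9 numeric matrix), `label4` (k x 4 character matrix),
#'   `key_ordered` / `key_multiset` (character vectors), and `edges`
#'   (2-column integer matrix of motif index pairs). A molecule with no
#'   3-hop path yields an empty motif graph.
#' @examples
#' cg <- cmotif_graph(chain_molecule(5))
#' nrow(cg$paths); nrow(cg$edges)
#' @export
cmotif_graph <- function(g, dedupe_reversed = FALSE) {
  paths <- khop_paths(g, 3L)
  if (dedupe_reversed && nrow(paths) > 0L) {
    fwd <- apply(paths, 1L, paste, collapse = ",")
    rev_ <- apply(paths[, 4:1, drop = FALSE], 1L, paste, collapse = ",")
    paths <- paths[fwd <= rev_, , drop = FALSE]
  }
  k <- nrow(paths)
  if (k == 0L) {
    return(structure(
      list(source = g$name, paths = paths,
           features = matrix(0, 0L, 9L),
           label4 = matrix(character(0), 0L, 4L),
           key_ordered = character(0), key_multiset = character(0),
           edges = matrix(integer(0), 0L, 2L)),
      class = "cmotif_graph"))
  }
  feats <- cmotif_feature_matrix(g, paths)
  label4 <- matrix(g$labels[paths], k, 4L)
  key_ordered <- apply(label4, 1L, label_key)
  key_multiset <- apply(label4, 1L, function(l) label_key(sort(l)))
  # motifs are adjacent iff their atom sets intersect: incidence crossprod
  inc <- matrix(0, k, length(g$labels))
  inc[cbind(rep(seq_len(k), 4L), as.vector(paths))] <- 1
  share <- inc %*% t(inc)
  idx <- which(share > 0 & upper.tri(share), arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2L)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(
    list(source = g$name, paths = paths, features = feats, label4 = label4,
         key_ordered = key_ordered, key_multiset = key_multiset,
         edges = edges),
    class = "cmotif_graph")
}

#' @export
print.cmotif_graph <- function(x, ...) {
  cat(sprintf("<cmotif_graph> %s: %d motifs, %d shared-atom edges\n",
              x$source, nrow(x$paths), nrow(x$edges)))
  invisible(x)
}
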