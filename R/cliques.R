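#' Enumerate maximal cliques of at least a given size
#'
#' A maximal clique is a complete subgraph not contained in any larger
#' complete subgraph. Maximal cliques of size at least 3 are the basic
#' cluster units of the CP-DR algorithm. Enumeration is delegated to
#' igraph's pivoting Bron-Kerbosch implementation; the result is returned
#' in a canonical order (size descending, then lexicographic on the sorted
#' member list) so downstream merging is deterministic.
#'
#' @param g An `igraph` graph with vertex names.
#' @param min_size Minimum clique size to report (>= 2).
#' @return A list of character vectors, each a sorted set of vertex names.
#' @export
#' @examples
#' g <- build_graph(data.frame(a = c("A", "B", "A"), b = c("B", "C", "C")))
#' maximal_cliques(g, 3)  # the triangle {A, B, C}
maximal_cliques <- function(g, min_size = 3L) {
  if (min_size < 2L) stop("min_size must be >= 2", call. = FALSE)
  if (igraph::vcount(g) == 0L) return(list())
  cl <- igraph::max_cliques(g, min = min_size)
  canonicalize_sets(lapply(cl, function(v) igraph::V(g)$name[as.integer(v)]))
}

#' Enumerate all k-cliques
#'
#' Returns every complete subgraph on exactly `k` vertices, the basic
#' topological unit of the clique percolation method.
#'
#' @param g An `igraph` graph with vertex names.
#' @param k Clique size (>= 2).
#' @return A list of character vectors in canonical order.
#' @export
k_cliques <- function(g, k) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (igraph::vcount(g) == 0L) return(list())
  cl <- igraph::cliques(g, min = k, max = k)
  canonicalize_sets(lapply(cl, function(v) igraph::V(g)$name[as.integer(v)]))
}

#' Clique-clique overlap matrix
#'
#' Entry (i, j) is the number of vertices shared by cliques i and j; the
#' diagonal entry (i, i) is the size of clique i. Thresholding this matrix
#' is how the clique percolation method extracts k-clique communities.
#'
#' @param cliques A list of vertex sets (character vectors).
#' @return A symmetric integer matrix.
#' @export
overlap_matrix <- function(cliques) {
  n <- length(cliques)
  m <- matrix(0L, n, n)
  if (n == 0L) return(m)
  for (i in seq_len(n)) {
    m[i, i] <- length(cliques[[i]])
    if (i < n) for (j in seq.int(i + 1L, n)) {
      ov <- length(intersect(cliques[[i]], cliques[[j]]))
      m[i, j] <- ov
      m[j, i] <- ov
    }
  }
  m
}

#' Write cliques or clusters to a file
#'
#' One vertex set per line, tab-separated sorted member identifiers.
#'
#' @param sets A list of character vectors.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_clusters <- function(sets, path) {
  sets <- canonicalize_sets(sets)
  write_lines_atomic(
    vapply(sets, paste, character(1), collapse = "\t"), path)
}

#' Read clusters from a file written by [write_clusters()]
#'
#' @param path Input file path.
#' @return A list of character vectors.
#' @export
read_clusters <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(strsplit(lines, "\t", fixed = TRUE), trimws)
}
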