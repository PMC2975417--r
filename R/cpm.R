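#' k-clique communities (clique percolation method, CPM)
#'
#' A k-clique community is the union of all k-cliques that can be reached
#' from one another through a chain of adjacent k-cliques, two k-cliques
#' being adjacent when they share k-1 vertices. The standard extraction
#' works on maximal cliques: (1) enumerate maximal cliques of size >= k;
#' (2) build the clique-clique overlap matrix; (3) zero off-diagonal
#' entries below k-1 and drop cliques whose diagonal entry is below k;
#' (4) each connected component of the surviving clique adjacency graph is
#' one community, its members the union of its cliques. Communities may
#' share vertices, but each maximal clique belongs to exactly one
#' community; a clique adjacent to no other forms a community by itself.
#'
#' @param g An `igraph` graph with vertex names.
#' @param k Percolation parameter (>= 3).
#' @return A list of character vectors (communities as sorted vertex
#'   sets), canonically ordered, with the contributing maximal cliques of
#'   each community attached as the `"cliques"` attribute and `k` as the
#'   `"k"` attribute.
#' @export
#' @examples
#' # two triangles sharing the edge {B, C} percolate into one community
#' g <- build_graph(data.frame(
#'   a = c("A", "A", "B", "B", "C"),
#'   b = c("B", "C", "C", "D", "D")))
#' kclique_communities(g, 3)
kclique_communities <- function(g, k) {
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  cl <- maximal_cliques(g, min_size = k)
  if (length(cl) == 0L) {
    return(structure(list(), k = k))
  }
  om <- overlap_matrix(cl)
  keep <- diag(om) >= k          # always true given min_size = k
  cl <- cl[keep]
  om <- om[keep, keep, drop = FALSE]
  adj <- om >= (k - 1L)
  diag(adj) <- FALSE
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(cg)$membership
  comms <- lapply(split(seq_along(cl), memb), function(idx) {
    sort(unique(unlist(cl[idx])), method = "radix")
  })
  prov <- split(cl, memb)
  ord <- canonical_set_order(comms)
  structure(comms[ord], cliques = unname(prov[ord]), k = k)
}
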