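#' Parameters for the CP-DR algorithm
#'
#' `d` is the maximum induced diameter (in hops) a cluster may have; the
#' default of 2 reflects the topology of curated yeast complexes, the
#' large majority of which have diameter at most 2. `min_clique_size` is
#' the minimum size of the maximal cliques used as basic cluster units.
#'
#' @param d Maximum induced diameter of a cluster (>= 1), default 2.
#' @param min_clique_size Minimum basic-unit clique size (>= 3), default 3.
#' @return A list of class `cpdr_params`.
#' @export
cpdr_params <- function(d = 2L, min_clique_size = 3L) {
  d <- as.integer(d); min_clique_size <- as.integer(min_clique_size)
  if (is.na(d) || d < 1L) stop("d must be >= 1", call. = FALSE)
  if (is.na(min_clique_size) || min_clique_size < 3L)
    stop("min_clique_size must be >= 3", call. = FALSE)
  structure(list(d = d, min_clique_size = min_clique_size),
            class = "cpdr_params")
}

#' Diameter of an induced subgraph
#'
#' The diameter of the subgraph of `g` induced by `members`: only edges
#' with both endpoints in `members` count, so paths may not detour through
#' outside vertices. A disconnected induced subgraph has diameter `Inf`
#' (it can never satisfy a finite distance restriction). A single vertex
#' has diameter 0.
#'
#' @param g An `igraph` graph with vertex names.
#' @param members Character vector of vertex names, all present in `g`.
#' @return A non-negative number, possibly `Inf`.
#' @export
induced_diameter <- function(g, members) {
  members <- unique(members)
  if (length(members) == 0L) stop("members must be non-empty", call. = FALSE)
  missing <- setdiff(members, igraph::V(g)$name)
  if (length(missing) > 0L)
    stop("vertex not in graph: ", missing[1L], call. = FALSE)
  if (length(members) == 1L) return(0)
  sub <- igraph::induced_subgraph(g, members)
  if (!igraph::is_connected(sub)) return(Inf)
  igraph::diameter(sub, unconnected = FALSE)
}

# Neighbor map (vertex name -> character vector of neighbor names) used by
# the merge scan to avoid constructing igraph subgraphs per pair.
neighbor_map <- function(g) {
  adj <- igraph::as_adj_list(g)
  nm <- igraph::V(g)$name
  out <- lapply(adj, function(v) nm[as.integer(v)])
  names(out) <- nm
  out
}

# TRUE iff the subgraph induced by `members` is connected with diameter
# <= d. The induced adjacency submatrix M is extracted from the neighbor
# map; reachability within d hops is M + M^2 + ... + M^d over the boolean
# semiring, and the test passes when every vertex pair is reachable.
induced_diam_le <- function(nbr, members, d) {
  m <- length(members)
  if (m <= 1L) return(TRUE)
  M <- vapply(members, function(v) members %in% nbr[[v]], logical(m))
  reach <- M
  depth <- 1L
  while (depth < d) {
    nxt <- reach | ((reach %*% M) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
    depth <- depth + 1L
  }
  diag(reach) <- TRUE
  all(reach)
}

#' Test whether two cluster units may merge
#'
#' Two basic cluster units U and V merge when both conditions hold:
#' \describe{
#'   \item{shared-vertex condition}{they have at least
#'     `N = min(|U|, |V|) - 1` vertices in common;}
#'   \item{distance restriction}{the subgraph induced by their union has
#'     diameter at most `d`.}
#' }
#' The adaptive threshold N makes merging as demanding as the smaller
#' unit allows (for two k-cliques it reduces to the k-1 adjacency of
#' clique percolation), while the distance restriction caps the spatial
#' extent of the growing cluster.
#'
#' @param g Host `igraph` graph.
#' @param u,v Vertex sets (character vectors) with distinct member sets.
#' @param params A [cpdr_params()] object.
#' @return `TRUE` or `FALSE`.
#' @export
merge_condition <- function(g, u, v, params = cpdr_params()) {
  n_required <- min(length(u), length(v)) - 1L
  if (length(intersect(u, v)) < n_required) return(FALSE)
  induced_diameter(g, union(u, v)) <= params$d
}

# Fast variant used inside the merge scan: same two conditions, with the
# diameter test run as a bounded BFS on a precomputed neighbor map.
merge_condition_nbr <- function(nbr, u, v, d) {
  n_required <- min(length(u), length(v)) - 1L
  if (length(intersect(u, v)) < n_required) return(FALSE)
  induced_diam_le(nbr, union(u, v), d)
}

#' Detect protein complexes with CP-DR
#'
#' CP-DR (clique percolation with distance restriction) proceeds in five
#' steps: (1) build the undirected simple graph; (2) enumerate maximal
#' cliques of size at least `min_clique_size`; (3) initialise each maximal
#' clique as a basic cluster unit; (4) repeatedly scan the unit pool: each
#' unit U is compared with every other unit V, each pair satisfying
#' [merge_condition()] appends the union of U and V at the tail of the
#' pool, and U is deleted once all its comparisons are done if it merged
#' at least once; (5) export the surviving units as clusters. Scans are
#' repeated until a full pass produces no merge, so the result does not
#' depend on a single pass's encounter order. When U merges with several
#' partners in one scan, one union per partner is created, which is how
#' overlapping clusters arise.
#'
#' Every emitted cluster is a union of maximal cliques with at least 3
#' vertices and induced diameter at most `params$d`. Exact duplicate
#' member sets are collapsed; clusters that are proper subsets of other
#' clusters are kept unless `absorb_subsets = TRUE`.
#'
#' @param g An `igraph` graph with vertex names (see [build_graph()]).
#' @param params A [cpdr_params()] object (defaults: d = 2,
#'   min_clique_size = 3).
#' @param absorb_subsets Drop clusters that are proper subsets of another
#'   cluster (default `FALSE`).
#' @param max_passes Safety cap on the number of full scan passes.
#' @param verbose Log the pool size after each pass.
#' @return A list of character vectors (clusters as sorted vertex sets) in
#'   canonical order, with the list of originating maximal cliques of each
#'   cluster attached as the `"provenance"` attribute.
#' @export
#' @examples
#' # two 4-cliques sharing the triangle {A, B, C} merge into one cluster
#' pairs <- rbind(
#'   t(combn(c("A", "B", "C", "D"), 2)),
#'   t(combn(c("A", "B", "C", "E"), 2)))
#' g <- build_graph(data.frame(a = pairs[, 1], b = pairs[, 2]))
#' cpdr_clusters(g)
cpdr_clusters <- function(g, params = cpdr_params(), absorb_subsets = FALSE,
                          max_passes = 1000L, verbose = FALSE) {
  stopifnot(inherits(params, "cpdr_params"))
  cliques <- maximal_cliques(g, params$min_clique_size)
  if (length(cliques) == 0L) return(structure(list(), provenance = list()))
  nm <- igraph::V(g)$name
  clique_ints <- lapply(cliques, function(cl) sort(match(cl, nm)))
  adj <- lapply(igraph::as_adj_list(g), as.integer)

  res <- .cpdr_merge_engine(clique_ints, adj, length(nm), params$d,
                            max_passes)
  if (verbose)
    message("fixpoint after ", res$passes, " passes; ",
            res$units_created, " units created, ",
            length(res$members), " clusters")

  pool <- lapply(res$members, function(ix) sort(nm[ix], method = "radix"))
  prov <- lapply(res$provenance, function(ix) cliques[ix])

  if (absorb_subsets && length(pool) > 1L) {
    ord <- canonical_set_order(pool)  # size descending
    pool <- pool[ord]; prov <- prov[ord]
    keep <- rep(TRUE, length(pool))
    for (i in seq_along(pool)) {
      if (!keep[i]) next
      for (j in seq_along(pool)) {
        if (i != j && keep[i] &&
            length(pool[[i]]) < length(pool[[j]]) &&
            all(pool[[i]] %in% pool[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    pool <- pool[keep]; prov <- prov[keep]
  }

  ord <- canonical_set_order(pool)
  structure(pool[ord], provenance = unname(prov[ord]))
}

# Reference implementation of the merge scan in plain R, list-based and
# deliberately literal. Semantically identical to the compiled engine;
# kept internal for cross-checking on small graphs.
cpdr_clusters_reference <- function(g, params = cpdr_params(),
                                    max_passes = 1000L) {
  stopifnot(inherits(params, "cpdr_params"))
  pool <- maximal_cliques(g, params$min_clique_size)
  if (length(pool) == 0L) return(structure(list(), provenance = list()))
  prov <- lapply(pool, list)
  keys <- vapply(pool, set_key, character(1))
  nbr <- neighbor_map(g)

  passes <- 0L
  repeat {
    passes <- passes + 1L
    if (passes > max_passes)
      stop("merge scan did not reach a fixpoint within ", max_passes,
           " passes", call. = FALSE)
    merged_in_pass <- FALSE
    i <- 1L
    while (i <= length(pool)) {
      u <- pool[[i]]
      merged_u <- FALSE
      j <- 1L
      while (j <= length(pool)) {  # pool grows as unions are appended
        if (j != i) {
          v <- pool[[j]]
          if (keys[[i]] != keys[[j]] &&
              merge_condition_nbr(nbr, u, v, params$d)) {
            w <- sort(union(u, v), method = "radix")
            wkey <- set_key(w)
            if (wkey == keys[[i]]) {
              # v contained in u: the union is u itself; not a merge for u
              prov[[i]] <- unique(c(prov[[i]], prov[[j]]))
            } else {
              merged_u <- TRUE
              merged_in_pass <- TRUE
              at <- match(wkey, keys)
              if (is.na(at)) {
                pool[[length(pool) + 1L]] <- w
                prov[[length(prov) + 1L]] <- unique(c(prov[[i]], prov[[j]]))
                keys <- c(keys, wkey)
              } else {
                prov[[at]] <- unique(c(prov[[at]], prov[[i]], prov[[j]]))
              }
            }
          }
        }
        j <- j + 1L
      }
      if (merged_u) {
        pool[[i]] <- NULL
        prov[[i]] <- NULL
        keys <- keys[-i]
      } else {
        i <- i + 1L
      }
    }
    if (!merged_in_pass) break
  }

  ord <- canonical_set_order(pool)
  structure(pool[ord], provenance = unname(prov[ord]))
}
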