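# Independent oracles used to cross-check the package's graph algorithms.
# All are deliberately naive (bitmask / exhaustive enumeration) and share
# no code with the implementations they validate.

# Random Erdos-Renyi test graph with vertex names. Caller controls the RNG.
random_test_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  g
}

# Maximal cliques by exhaustive bitmask enumeration (n <= ~15).
# A subset is a clique iff every member is adjacent to all other members;
# it is maximal iff no outside vertex is adjacent to all members.
oracle_maximal_cliques <- function(g, min_size) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  bit <- 2^(seq_len(n) - 1)
  nbr_mask <- vapply(seq_len(n), function(v) sum(bit[A[v, ]]), numeric(1))
  res <- list()
  for (mask in seq_len(2^n - 1)) {
    vs <- which(bitwAnd(mask, bit) != 0)
    if (length(vs) < min_size) next
    is_clique <- all(vapply(vs, function(v) {
      rest <- mask - bit[v]
      bitwAnd(rest, nbr_mask[v]) == rest
    }, logical(1)))
    if (!is_clique) next
    outside <- setdiff(seq_len(n), vs)
    extendable <- any(vapply(outside, function(o)
      bitwAnd(mask, nbr_mask[o]) == mask, logical(1)))
    if (!extendable) res[[length(res) + 1L]] <- nm[vs]
  }
  lapply(res, sort, method = "radix")
}

# All complete subgraphs on exactly k vertices, by checking every k-subset.
oracle_k_cliques <- function(g, k) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n < k) return(list())
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  subs <- utils::combn(seq_len(n), k)
  res <- list()
  for (c_i in seq_len(ncol(subs))) {
    vs <- subs[, c_i]
    prs <- utils::combn(vs, 2L)
    if (all(A[cbind(prs[1L, ], prs[2L, ])]))
      res[[length(res) + 1L]] <- sort(nm[vs], method = "radix")
  }
  res
}

# Direct k-clique percolation: adjacency between exact k-cliques sharing
# k-1 vertices, connected components, union of members. This is the
# definitional form of CPM, independent of the overlap-matrix procedure.
oracle_kclique_percolation <- function(g, k) {
  kc <- oracle_k_cliques(g, k)
  m <- length(kc)
  if (m == 0L) return(list())
  adj <- matrix(FALSE, m, m)
  if (m > 1L) for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    adj[i, j] <- adj[j, i] <-
      length(intersect(kc[[i]], kc[[j]])) == k - 1L
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  comms <- lapply(split(seq_len(m), comp$membership), function(idx)
    sort(unique(unlist(kc[idx])), method = "radix"))
  unname(comms)
}

# Hypergeometric upper tail as an explicit sum of binomial-coefficient
# terms.
oracle_hyper_tail <- function(n_total, c_size, f_size, k_hit) {
  i <- seq.int(k_hit, min(c_size, f_size))
  sum(choose(f_size, i) * choose(n_total - f_size, c_size - i)) /
    choose(n_total, c_size)
}

# Exact diameter of an induced subgraph via Floyd-Warshall on the member
# adjacency submatrix.
oracle_induced_diameter <- function(g, members) {
  m <- length(members)
  if (m == 1L) return(0)
  A <- as.matrix(igraph::as_adjacency_matrix(g))[members, members] > 0
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  max(D)
}

# Sets-of-sets equality up to order.
same_set_family <- function(a, b) {
  key <- function(s) paste(sort(s), collapse = "\t")
  setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
}

# Build a named igraph from a two-column character matrix of edges.
graph_from_pairs <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  build_graph(data.frame(protein_a = e[, 1], protein_b = e[, 2],
                         stringsAsFactors = FALSE))
}

# Complete graph on the given named vertices.
complete_graph <- function(ids) {
  p <- utils::combn(ids, 2L)
  build_graph(data.frame(protein_a = p[1L, ], protein_b = p[2L, ],
                         stringsAsFactors = FALSE))
}
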