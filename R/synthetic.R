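#' Generate a planted-overlapping-complex benchmark graph
#'
#' Builds a graph with known ground truth for testing complex-detection
#' algorithms. `n_complexes` vertex sets are planted in a chain:
#' consecutive complexes share `overlap_size` vertices, so the expected
#' behaviour of merge rules on each adjacent pair is analytically
#' derivable. Complex sizes are drawn uniformly from
#' `[size_min, size_max]` — the meso-scale range (roughly 5-25 proteins)
#' typical of curated complexes. Within each complex every vertex pair is
#' an edge with probability `intra_density` (1 plants true cliques);
#' `noise_edges` additional random edges are then added between pairs not
#' inside any planted complex. The graph is simple (no self-loops or
#' duplicates) and fully reproducible from `seed`; the caller's RNG state
#' is untouched.
#'
#' Vertices that end up with no incident edge (possible when
#' `intra_density < 1`) do not appear in the graph, matching the
#' edge-list-defined graphs produced by [build_graph()].
#'
#' @param n_complexes Number of planted complexes, default 10.
#' @param size_min,size_max Complex size range, defaults 5 and 25.
#' @param overlap_size Vertices shared by consecutive complexes
#'   (< `size_min`), default 2.
#' @param intra_density Within-complex edge probability in (0, 1\],
#'   default 1.
#' @param noise_edges Number of random background edges, default 50.
#' @param seed Integer seed governing all randomness (required).
#' @return A list of class `planted_benchmark` with elements `graph`
#'   (igraph), `truth` (list of character vectors, canonical order) and
#'   `params`.
#' @export
#' @examples
#' b <- generate_benchmark(n_complexes = 3, size_min = 5, size_max = 5,
#'                         overlap_size = 0, noise_edges = 0, seed = 7)
#' igraph::vcount(b$graph); igraph::ecount(b$graph)  # 15, 30
generate_benchmark <- function(n_complexes = 10L, size_min = 5L,
                               size_max = 25L, overlap_size = 2L,
                               intra_density = 1, noise_edges = 50L,
                               seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (size_min < 3L) stop("size_min must be >= 3", call. = FALSE)
  if (size_max < size_min) stop("size_max must be >= size_min", call. = FALSE)
  if (overlap_size >= size_min)
    stop("overlap_size must be smaller than size_min", call. = FALSE)
  if (overlap_size < 0L) stop("overlap_size must be >= 0", call. = FALSE)
  if (intra_density <= 0 || intra_density > 1)
    stop("intra_density must be in (0, 1]", call. = FALSE)
  if (n_complexes < 1L) stop("n_complexes must be >= 1", call. = FALSE)

  with_preserved_seed(seed, {
    sizes <- if (size_min == size_max) rep(size_min, n_complexes) else
      sample(seq.int(size_min, size_max), n_complexes, replace = TRUE)

    next_id <- 1L
    fresh <- function(n) {
      ids <- sprintf("P%04d", seq.int(next_id, length.out = n))
      next_id <<- next_id + n
      ids
    }
    truth <- vector("list", n_complexes)
    for (ci in seq_len(n_complexes)) {
      if (ci == 1L || overlap_size == 0L) {
        truth[[ci]] <- fresh(sizes[ci])
      } else {
        shared <- sample(truth[[ci - 1L]], overlap_size)
        truth[[ci]] <- c(shared, fresh(sizes[ci] - overlap_size))
      }
    }

    edges <- character(0)
    for (members in truth) {
      pairs <- utils::combn(sort(members, method = "radix"), 2L)
      if (intra_density < 1) {
        keep <- stats::runif(ncol(pairs)) <= intra_density
        pairs <- pairs[, keep, drop = FALSE]
      }
      if (ncol(pairs) > 0L)
        edges <- c(edges, paste(pairs[1L, ], pairs[2L, ], sep = "\t"))
    }
    edges <- unique(edges)
    intra_universe <- unique(unlist(lapply(truth, function(m) {
      p <- utils::combn(sort(m, method = "radix"), 2L)
      paste(p[1L, ], p[2L, ], sep = "\t")
    })))

    all_ids <- sprintf("P%04d", seq_len(next_id - 1L))
    noise <- character(0)
    attempts <- 0L
    while (length(noise) < noise_edges && attempts < 100L * noise_edges + 100L) {
      attempts <- attempts + 1L
      pair <- sample(all_ids, 2L)
      key <- paste(min(pair), max(pair), sep = "\t")
      if (!(key %in% intra_universe) && !(key %in% noise))
        noise <- c(noise, key)
    }
    if (length(noise) < noise_edges)
      stop("could not place ", noise_edges, " noise edges", call. = FALSE)

    all_edges <- c(edges, noise)
    parts <- strsplit(all_edges, "\t", fixed = TRUE)
    g <- build_graph(data.frame(
      protein_a = vapply(parts, `[[`, character(1), 1L),
      protein_b = vapply(parts, `[[`, character(1), 2L),
      stringsAsFactors = FALSE))

    structure(list(
      graph = g,
      truth = canonicalize_sets(truth),
      params = list(n_complexes = n_complexes, size_min = size_min,
                    size_max = size_max, overlap_size = overlap_size,
                    intra_density = intra_density,
                    noise_edges = noise_edges, seed = seed)
    ), class = "planted_benchmark")
  })
}

#' Write a benchmark to disk
#'
#' Writes `<prefix>.edges.tsv` (canonical edge list) and
#' `<prefix>.truth.tsv` (one planted complex per line, tab-separated
#' sorted identifiers), the formats consumed by the rest of the package.
#'
#' @param bench A `planted_benchmark` from [generate_benchmark()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_benchmark <- function(bench, prefix) {
  stopifnot(inherits(bench, "planted_benchmark"))
  edges_path <- paste0(prefix, ".edges.tsv")
  truth_path <- paste0(prefix, ".truth.tsv")
  write_interactions(bench$graph, edges_path)
  write_clusters(bench$truth, truth_path)
  invisible(c(edges_path, truth_path))
}
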