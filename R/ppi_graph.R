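#' Read a protein-protein interaction edge list
#'
#' Parses a delimited text file (or connection) with one interaction per
#' line: two or more delimited fields, of which the first two are the
#' interacting protein identifiers. Lines starting with `#` and blank lines
#' are skipped; extra columns are ignored. Parsing is faithful to the file:
#' self-interactions and duplicate pairs are kept here and removed later by
#' [build_graph()].
#'
#' @param source Path to a text file, or a connection.
#' @param delimiter Field separator, default tab.
#' @return A `data.frame` with character columns `protein_a` and
#'   `protein_b`, one row per data line in file order.
#' @seealso [build_graph()]
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# my network", "A\tB", "B\tC"), f)
#' load_interactions(f)
load_interactions <- function(source, delimiter = "\t") {
  lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- line_no[which(nf < 2L)[1L]]
    stop("malformed interaction line ", bad, ": fewer than 2 fields",
         call. = FALSE)
  }
  a <- trimws(vapply(fields, `[[`, character(1), 1L))
  b <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    bad <- line_no[which(!nzchar(a) | !nzchar(b))[1L]]
    stop("malformed interaction line ", bad, ": empty protein identifier",
         call. = FALSE)
  }
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

#' Build an undirected simple interaction graph
#'
#' Turns a table of pairwise interactions into an undirected simple
#' `igraph` graph: self-interactions are dropped, duplicate pairs (in
#' either order) are collapsed to a single edge, and the vertex set is the
#' set of endpoints of the surviving edges. Proteins appearing only in
#' self-interactions are therefore not vertices; they would be isolated and
#' play no role in clique-based clustering.
#'
#' Identifiers are treated as opaque, case-sensitive strings.
#'
#' @param interactions A two-column `data.frame` as returned by
#'   [load_interactions()] (columns `protein_a`, `protein_b`), or any
#'   data.frame whose first two columns are protein identifiers.
#' @return An undirected simple `igraph` object with vertex names.
#' @export
#' @examples
#' g <- build_graph(data.frame(protein_a = c("A", "B", "A", "B"),
#'                             protein_b = c("B", "A", "A", "C")))
#' igraph::vcount(g); igraph::ecount(g)  # 3 vertices, 2 edges
build_graph <- function(interactions) {
  a <- trimws(as.character(interactions[[1L]]))
  b <- trimws(as.character(interactions[[2L]]))
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\t"))
  lo <- lo[!dup]; hi <- hi[!dup]
  igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
}

#' Descriptive statistics of an interaction network
#'
#' Computes the summary statistics used to characterise a PPI network:
#' vertex and edge counts, the average local clustering coefficient, and
#' the diameter and average shortest-path length. Degree-0/1 vertices
#' contribute a local clustering coefficient of 0 (they are not excluded
#' from the mean). Because real interaction networks are usually
#' disconnected, diameter and average path length are computed over the
#' largest connected component.
#'
#' @param g An `igraph` graph from [build_graph()].
#' @return A list of class `network_stats` with elements `n_vertices`,
#'   `n_edges`, `avg_clustering_coefficient`, `diameter` and
#'   `avg_shortest_path` (the last two over the largest component).
#' @export
network_stats <- function(g) {
  if (igraph::vcount(g) == 0L) stop("graph is empty", call. = FALSE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0  # degree-1 vertices
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  if (igraph::vcount(giant) >= 2L) {
    diam <- igraph::diameter(giant, unconnected = FALSE)
    apl <- igraph::mean_distance(giant, unconnected = FALSE)
  } else {
    diam <- 0
    apl <- 0
  }
  structure(list(
    n_vertices = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    avg_clustering_coefficient = mean(cc),
    diameter = diam,
    avg_shortest_path = apl
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  for (nm in names(x)) cat(nm, "\t", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Write an interaction graph as a canonical edge list
#'
#' The output is round-trippable through [load_interactions()] +
#' [build_graph()]: each edge is written once as a tab-separated pair with
#' the lexicographically smaller identifier first, lines sorted.
#'
#' @param g An `igraph` graph with vertex names.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_interactions <- function(g, path) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) return(write_lines_atomic(character(0), path))
  lo <- pmin(el[, 1L], el[, 2L])
  hi <- pmax(el[, 1L], el[, 2L])
  write_lines_atomic(sort(paste(lo, hi, sep = "\t"), method = "radix"), path)
}
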