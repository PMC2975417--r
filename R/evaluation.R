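#' Overlap score between a predicted cluster and a known complex
#'
#' `OS(Pc, Kc) = i^2 / (|Pc| * |Kc|)` where `i` is the number of shared
#' proteins. The score is symmetric, 0 when the sets are disjoint and 1
#' when they coincide. The conventional match threshold is 0.2.
#'
#' @param pc,kc Non-empty character vectors of protein identifiers.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' overlap_score(c("A", "B", "C", "D"), c("A", "B", "X", "Y"))  # 4/16
overlap_score <- function(pc, kc) {
  pc <- unique(pc); kc <- unique(kc)
  if (length(pc) == 0L || length(kc) == 0L)
    stop("overlap_score requires non-empty sets", call. = FALSE)
  i <- length(intersect(pc, kc))
  i^2 / (length(pc) * length(kc))
}

#' Match predicted clusters against a gold-standard catalog
#'
#' A predicted cluster is a true positive when its best overlap score
#' against any known complex reaches `threshold`; a known complex is
#' matched when some predicted cluster reaches `threshold` against it.
#' Both directions are counted, because the number of matched predictions
#' and the number of matched known complexes generally differ (several
#' predictions can match one complex and vice versa).
#'
#' @param predicted List of character vectors (predicted clusters).
#' @param known Named list of character vectors (known complexes), e.g.
#'   from [load_complex_catalog()].
#' @param threshold Overlap-score cutoff in (0, 1], default 0.2.
#' @return A list of class `match_result` with elements `tp`, `fp`,
#'   `matched_known`, `fn`, `threshold`, `n_predicted`, `n_known`, and
#'   `best_os` (per-predicted-cluster best overlap score).
#' @export
match_complexes <- function(predicted, known, threshold = 0.2) {
  if (length(known) == 0L) stop("known catalog is empty", call. = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  best_pred <- if (length(predicted) == 0L) numeric(0) else
    vapply(predicted, function(pc)
      max(vapply(known, function(kc) overlap_score(pc, kc), numeric(1))),
      numeric(1))
  best_known <- vapply(known, function(kc) {
    if (length(predicted) == 0L) return(0)
    max(vapply(predicted, function(pc) overlap_score(pc, kc), numeric(1)))
  }, numeric(1))
  tp <- sum(best_pred >= threshold)
  matched_known <- sum(best_known >= threshold)
  structure(list(
    tp = tp,
    fp = length(predicted) - tp,
    matched_known = matched_known,
    fn = length(known) - matched_known,
    threshold = threshold,
    n_predicted = length(predicted),
    n_known = length(known),
    best_os = best_pred
  ), class = "match_result")
}

#' Sensitivity, specificity and f-measure
#'
#' `sensitivity = TP / (TP + FN)`: the fraction of true predictions that
#' were recovered. `specificity = TP / (TP + FP)`: the fraction of
#' predictions that are true. `f_measure` combines the two as their
#' harmonic mean, `2 * Sn * Sp / (Sn + Sp)`.
#'
#' @param tp,fn,fp Non-negative counts.
#' @param sn,sp Fractions in \[0, 1\], not both zero.
#' @return A fraction in \[0, 1\].
#' @export
sensitivity <- function(tp, fn) {
  if (tp + fn <= 0) stop("tp + fn must be positive", call. = FALSE)
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(tp, fp) {
  if (tp + fp <= 0) stop("tp + fp must be positive", call. = FALSE)
  tp / (tp + fp)
}

#' @rdname sensitivity
#' @export
f_measure <- function(sn, sp) {
  if (sn + sp <= 0) stop("sn + sp must be positive", call. = FALSE)
  2 * sn * sp / (sn + sp)
}

#' Overlapping rate of a set of predicted clusters
#'
#' The average number of clusters each covered protein belongs to:
#' the sum of cluster sizes divided by the number of distinct proteins
#' that appear in at least one cluster. Proteins in no cluster are not
#' counted. Also reports the fraction of covered proteins belonging to
#' more than one cluster.
#'
#' @param predicted Non-empty list of non-empty character vectors.
#' @return A list with elements `rate` (>= 1) and `frac_multi` in
#'   \[0, 1\].
#' @export
#' @examples
#' overlapping_rate(list(c("A", "B", "C"), c("A", "D", "E")))  # 6/5
overlapping_rate <- function(predicted) {
  if (length(predicted) == 0L) stop("no clusters given", call. = FALSE)
  predicted <- lapply(predicted, unique)
  if (any(lengths(predicted) == 0L))
    stop("clusters must be non-empty", call. = FALSE)
  occ <- table(unlist(predicted))
  list(rate = sum(lengths(predicted)) / length(occ),
       frac_multi = mean(occ > 1L))
}

#' Hypergeometric enrichment P-value
#'
#' Upper-tail probability that a cluster of size `c_size` drawn from a
#' network of `n_total` proteins contains at least `k_hit` members of a
#' functional group of size `f_size`:
#' `P = sum_{i = k_hit}^{min(C, F)} choose(F, i) choose(N - F, C - i) /
#' choose(N, C)`. The observed count is included in the tail, so
#' `k_hit = 0` gives 1.
#'
#' @param n_total Total number of proteins in the network (N).
#' @param c_size Cluster size (C).
#' @param f_size Functional-group size (F).
#' @param k_hit Number of cluster members in the group (k).
#' @return A probability in (0, 1\].
#' @export
hypergeom_pvalue <- function(n_total, c_size, f_size, k_hit) {
  if (k_hit < 0 || c_size > n_total || f_size > n_total ||
      k_hit > min(c_size, f_size))
    stop("require 0 <= k_hit <= min(c_size, f_size) <= n_total",
         call. = FALSE)
  if (k_hit == 0L) return(1)
  stats::phyper(k_hit - 1, f_size, n_total - f_size, c_size,
                lower.tail = FALSE)
}

#' Assign a cluster its main function by minimum enrichment P-value
#'
#' Evaluates [hypergeom_pvalue()] for every annotation category hit by at
#' least one cluster member and returns the category with the smallest
#' P-value; ties are broken by the lexicographically smallest category
#' code. Category sizes (`F`) are the number of annotated proteins
#' carrying each code in the supplied annotation map; dotted codes are
#' treated as independent categories with no hierarchy propagation.
#'
#' @param cluster Character vector of protein identifiers.
#' @param annotations Named list mapping protein identifier to a character
#'   vector of category codes (see [load_annotations()]).
#' @param n_total Total number of proteins in the network (N).
#' @return A list with elements `best_category` (code or `NA` when no
#'   member is annotated), `p_value`, `k_in`, and `n_categories_tested`.
#' @export
assign_main_function <- function(cluster, annotations, n_total) {
  cluster <- unique(cluster)
  member_codes <- annotations[intersect(cluster, names(annotations))]
  if (length(member_codes) == 0L) {
    return(list(best_category = NA_character_, p_value = NA_real_,
                k_in = 0L, n_categories_tested = 0L))
  }
  cats <- sort(unique(unlist(member_codes)), method = "radix")
  f_sizes <- table(unlist(lapply(annotations, unique)))
  pvals <- vapply(cats, function(cat) {
    k <- sum(vapply(member_codes, function(cc) cat %in% cc, logical(1)))
    hypergeom_pvalue(n_total, length(cluster),
                     as.integer(f_sizes[[cat]]), k)
  }, numeric(1))
  best <- cats[which.min(pvals)]  # ties: first in sorted code order
  k_best <- sum(vapply(member_codes, function(cc) best %in% cc, logical(1)))
  list(best_category = best, p_value = unname(min(pvals)),
       k_in = k_best, n_categories_tested = length(cats))
}

#' Complex-complex overlap network
#'
#' Emits one pair `(i, j)`, `i < j`, for every two clusters sharing at
#' least one protein. Isolated clusters appear in no pair.
#'
#' @param predicted List of character vectors.
#' @return A two-column integer matrix (columns `i`, `j`) of 1-based
#'   cluster indices; zero rows when no clusters overlap.
#' @export
complex_overlap_network <- function(predicted) {
  n <- length(predicted)
  out <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (length(intersect(predicted[[i]], predicted[[j]])) > 0L)
      out[[length(out) + 1L]] <- c(i, j)
  }
  m <- if (length(out) == 0L) matrix(integer(0), 0L, 2L) else
    do.call(rbind, out)
  colnames(m) <- c("i", "j")
  m
}

#' Read a gold-standard complex catalog
#'
#' One complex per line: the first tab-separated token is the complex
#' name, the remaining tokens its protein identifiers. Complexes with
#' fewer than two distinct proteins are discarded.
#'
#' @param path Input file path.
#' @return A named list of character vectors.
#' @export
load_complex_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    toks <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2L) next
    members <- unique(toks[-1L])
    if (length(members) >= 2L) out[[toks[1L]]] <- sort(members,
                                                       method = "radix")
  }
  out
}

#' Read protein functional annotations
#'
#' Two tab-separated columns per line: protein identifier and dotted
#' category code. A protein may appear on several lines.
#'
#' @param path Input file path.
#' @return A named list mapping protein identifier to a character vector
#'   of category codes.
#' @export
load_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L)
    stop("malformed annotation line ", bad[1L], call. = FALSE)
  prot <- trimws(vapply(toks, `[[`, character(1), 1L))
  code <- trimws(vapply(toks, `[[`, character(1), 2L))
  lapply(split(code, prot), function(x) sort(unique(x), method = "radix"))
}

#' Evaluate predicted clusters against a catalog (and annotations)
#'
#' Convenience wrapper producing the full evaluation report: match counts
#' at the overlap-score threshold, sensitivity / specificity / f-measure,
#' overlapping rate, the complex-complex overlap pairs, and (when
#' annotations are supplied) the per-cluster main-function enrichment.
#' Sensitivity uses the matched-known count against the full catalog size
#' by default; `known_denominator` overrides the denominator when a
#' different reference-set size is wanted.
#'
#' @param predicted List of character vectors.
#' @param known Named list of character vectors.
#' @param threshold Overlap-score cutoff, default 0.2.
#' @param annotations Optional annotation map from [load_annotations()].
#' @param n_total Network size for enrichment; required with
#'   `annotations`.
#' @param known_denominator Optional alternative denominator for
#'   sensitivity (defaults to the number of known complexes).
#' @return A list of class `eval_report`.
#' @export
evaluate_clusters <- function(predicted, known, threshold = 0.2,
                              annotations = NULL, n_total = NULL,
                              known_denominator = NULL) {
  mr <- match_complexes(predicted, known, threshold)
  denom <- if (is.null(known_denominator)) mr$n_known else known_denominator
  sn <- mr$matched_known / denom
  sp <- specificity(mr$tp, mr$fp)
  fm <- if (sn + sp > 0) f_measure(sn, sp) else 0
  ovr <- if (length(predicted) > 0L) overlapping_rate(predicted) else
    list(rate = NA_real_, frac_multi = NA_real_)
  enrich <- NULL
  if (!is.null(annotations)) {
    if (is.null(n_total))
      stop("n_total is required for enrichment", call. = FALSE)
    enrich <- lapply(predicted, assign_main_function, annotations, n_total)
  }
  structure(list(
    match = mr, sensitivity = sn, specificity = sp, f_measure = fm,
    overlapping_rate = ovr$rate, frac_multi = ovr$frac_multi,
    overlap_pairs = complex_overlap_network(predicted),
    enrichment = enrich
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$match
  cat("predicted\t", m$n_predicted, "\n", sep = "")
  cat("known\t", m$n_known, "\n", sep = "")
  cat("threshold\t", m$threshold, "\n", sep = "")
  cat("tp\t", m$tp, "\n", sep = "")
  cat("fp\t", m$fp, "\n", sep = "")
  cat("matched_known\t", m$matched_known, "\n", sep = "")
  cat("fn\t", m$fn, "\n", sep = "")
  cat("sensitivity\t", format(x$sensitivity), "\n", sep = "")
  cat("specificity\t", format(x$specificity), "\n", sep = "")
  cat("f_measure\t", format(x$f_measure), "\n", sep = "")
  cat("overlapping_rate\t", format(x$overlapping_rate), "\n", sep = "")
  cat("frac_multi\t", format(x$frac_multi), "\n", sep = "")
  if (!is.null(x$enrichment)) {
    p <- vapply(x$enrichment, function(e)
      if (is.na(e$p_value)) NA_real_ else e$p_value, numeric(1))
    cat("enriched_p0.01\t", sum(p < 0.01, na.rm = TRUE), "\n", sep = "")
    cat("enriched_p0.001\t", sum(p < 0.001, na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}
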