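# Internal helpers shared across modules.

# Canonical ordering of a list of vertex sets: size descending, then
# lexicographic on the tab-joined sorted member list.  Radix ordering keeps
# the result locale-independent, so output files are byte-reproducible.
canonical_set_order <- function(sets) {
  if (length(sets) == 0L) return(integer(0))
  sizes <- lengths(sets)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "\t"), character(1))
  order(-sizes, keys, method = "radix")
}

# Sort members within each set and order the list canonically.
canonicalize_sets <- function(sets) {
  sets <- lapply(sets, function(s) sort(s, method = "radix"))
  sets[canonical_set_order(sets)]
}

set_key <- function(s) paste(sort(s, method = "radix"), collapse = "\t")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state.
with_preserved_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Write lines atomically: temp file in the target directory, then rename.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wt", encoding = "UTF-8")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con)
    close(con)
    ok <- TRUE
  }, finally = {
    if (!ok) {
      try(close(con), silent = TRUE)
      unlink(tmp)
    }
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("failed to write ", path, call. = FALSE)
  }
  invisible(path)
}
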