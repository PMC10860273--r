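# Internal helpers shared across modules.

#' Emit a progress/log message unless quiet
#'
#' All informational output goes through this wrapper so that
#' `options(ctnet.quiet = TRUE)` silences the package.
#' @noRd
ct_log <- function(...) {
  if (!isTRUE(getOption("ctnet.quiet", FALSE))) {
    inform(paste0(...), class = "ctnet_log")
  }
  invisible(NULL)
}

#' Evaluate code under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so stochastic stages are
#' reproducible without clobbering the session seed.
#' @noRd
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Canonicalize an undirected edge table
#'
#' Orders each endpoint pair lexicographically, drops self-loops, and
#' deduplicates (first occurrence wins for any extra columns). Returns the
#' cleaned tibble plus the number of self-loops and duplicates removed.
#' @noRd
canonicalize_edges <- function(edges) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges <- as_tibble(edges)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  loops <- edges$from == edges$to
  edges <- edges[!loops, , drop = FALSE]
  key <- paste(edges$from, edges$to, sep = "\r")
  dup <- duplicated(key)
  edges <- edges[!dup, , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  list(edges = edges, n_self_loops = sum(loops), n_duplicates = sum(dup))
}

edge_key <- function(edges) paste(edges$from, edges$to, sep = "\r")

#' Order genes best-first by a named score, ties broken by symbol
#'
#' @param scores named numeric vector; larger is better.
#' @return character vector of names in ranking order.
#' @export
rank_genes <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  names(scores)[order(-scores, names(scores))]
}

# zero-padded synthetic identifiers: g0001, c0001, ...
padded_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}
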