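# Network containers: the reference interactome and per-cell-type networks.
#
# Both are light S3 wrappers around a canonical tibble edge table
# (columns from, to, plus weight / q_value where relevant) with an explicit
# node set, so isolated nodes survive subsetting.

#' Construct a reference interactome
#'
#' An undirected simple graph over gene symbols, optionally carrying a
#' non-negative confidence weight per edge (e.g. a database score). Edges are
#' canonicalized lexicographically, self-loops dropped and duplicates removed.
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`.
#' @param name label for the reference (used as `parent` in derived networks).
#' @param nodes optional character vector of nodes; defaults to the edge
#'   endpoints. Must cover all endpoints.
#' @return an object of class `interactome`.
#' @export
interactome <- function(edges, name = "reference", nodes = NULL) {
  cleaned <- canonicalize_edges(edges)
  edges <- cleaned$edges
  if (cleaned$n_self_loops > 0)
    ct_log("interactome: dropped ", cleaned$n_self_loops, " self-loop(s)")
  if (cleaned$n_duplicates > 0)
    ct_log("interactome: dropped ", cleaned$n_duplicates, " duplicate edge(s)")
  if ("weight" %in% names(edges)) {
    w <- edges$weight
    if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0))
      abort("interactome prior weights must be finite and non-negative")
  }
  endpoint <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- endpoint
  } else {
    nodes <- unique(as.character(nodes))
    if (!all(endpoint %in% nodes))
      abort("`nodes` must contain every edge endpoint")
  }
  structure(
    list(edges = edges, nodes = sort(nodes), name = name),
    class = "interactome"
  )
}

#' Construct a cell-type-specific network
#'
#' A weighted subgraph of a reference interactome specific to one cell type.
#' Edge weights are the interaction strengths assigned by reconstruction and
#' must be strictly positive.
#'
#' @param edges data frame with columns `from`, `to`, `weight` and optionally
#'   `q_value`.
#' @param cell_type cell-type label.
#' @param parent name of the reference interactome the network was carved from.
#' @param nodes optional node set (defaults to edge endpoints).
#' @return an object of class `ct_network`.
#' @export
ct_network <- function(edges, cell_type = "celltype", parent = NA_character_,
                       nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(),
                    weight = numeric())
  }
  cleaned <- canonicalize_edges(edges)
  edges <- cleaned$edges
  if (!"weight" %in% names(edges))
    abort("ct_network edges require a `weight` column")
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
    abort("ct_network edge weights must be finite and > 0")
  if ("q_value" %in% names(edges) &&
      any(edges$q_value < 0 | edges$q_value > 1, na.rm = TRUE))
    abort("edge q-values must lie in [0, 1]")
  endpoint <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- endpoint
  } else {
    nodes <- unique(as.character(nodes))
    if (!all(endpoint %in% nodes))
      abort("`nodes` must contain every edge endpoint")
  }
  structure(
    list(edges = edges, nodes = sort(nodes), cell_type = cell_type,
         parent = parent),
    class = "ct_network"
  )
}

#' Nodes of a network object
#' @param x an `interactome` or `ct_network`.
#' @return character vector of gene symbols.
#' @export
network_nodes <- function(x) {
  stopifnot(inherits(x, c("interactome", "ct_network")))
  x$nodes
}

#' Edge table of a network object
#' @param x an `interactome` or `ct_network`.
#' @return tibble with columns `from`, `to` and any edge attributes.
#' @export
network_edges <- function(x) {
  stopifnot(inherits(x, c("interactome", "ct_network")))
  x$edges
}

#' Convert a network object to an igraph graph
#'
#' @param x an `interactome` or `ct_network`.
#' @return an undirected [igraph::igraph] graph carrying edge weights.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, c("interactome", "ct_network")))
  g <- igraph::graph_from_data_frame(as.data.frame(x$edges), directed = FALSE,
                                     vertices = x$nodes)
  g
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", x$name, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges",
      if ("weight" %in% names(x$edges)) " (weighted)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.ct_network <- function(x, ...) {
  cat("<ct_network> ", x$cell_type, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (parent: ", x$parent, ")\n", sep = "")
  invisible(x)
}

#' @describeIn ct_network edge table of a cell-type network as a tibble.
#' @param x a `ct_network`.
#' @param ... unused.
#' @method tidy ct_network
#' @export
tidy.ct_network <- function(x, ...) {
  mutate(x$edges, cell_type = x$cell_type)
}

#' @method glance ct_network
#' @export
glance.ct_network <- function(x, ...) {
  tibble(
    cell_type = x$cell_type,
    parent = x$parent,
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    total_weight = sum(x$edges$weight)
  )
}

# ---- readers / writers ------------------------------------------------------

#' Read an undirected edge list from TSV
#'
#' Expects at least two tab-separated columns (geneA, geneB) and, with
#' `has_weight = TRUE`, a numeric third column. A header line is detected
#' automatically (non-numeric third field, or a first line starting with
#' `geneA`). Endpoint order is canonicalized, duplicate edges are collapsed
#' and self-loops dropped with a logged count.
#'
#' @param path path to a TSV file.
#' @param has_weight read the third column as a confidence weight.
#' @param name label for the resulting interactome.
#' @return an [interactome].
#' @export
read_edge_list <- function(path, has_weight = FALSE, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("empty edge-list file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  first <- fields[[1]]
  is_header <- identical(tolower(first[1]), "genea") ||
    identical(tolower(first[1]), "from") ||
    (has_weight && length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
  if (is_header) start <- 2L
  if (start > length(fields)) {
    return(interactome(tibble(from = character(), to = character()), name = name))
  }
  need <- if (has_weight) 3L else 2L
  rows <- fields[start:length(fields)]
  bad <- which(vapply(rows, length, 1L) < need)
  if (length(bad) > 0)
    abort(paste0("malformed row at line ", bad[1] + start - 1L, " of ", path,
                 ": expected at least ", need, " fields"))
  from <- vapply(rows, `[[`, "", 1L)
  to <- vapply(rows, `[[`, "", 2L)
  edges <- tibble(from = from, to = to)
  if (has_weight) {
    w <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
    if (any(is.na(w))) {
      abort(paste0("non-numeric weight at line ",
                   which(is.na(w))[1] + start - 1L, " of ", path))
    }
    edges$weight <- w
  }
  interactome(edges, name = name)
}

#' Write a network to TSV or GraphML
#'
#' The TSV format has a header `geneA geneB weight` (weight printed with 12
#' significant digits); GraphML is written via igraph and carries the weight
#' as an edge attribute.
#'
#' @param network an `interactome` or `ct_network`.
#' @param path output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, c("interactome", "ct_network")))
  edges <- network$edges
  if (format == "tsv") {
    w <- if ("weight" %in% names(edges)) sprintf("%.12g", edges$weight) else
      rep("1", nrow(edges))
    out <- c("geneA\tgeneB\tweight",
             if (nrow(edges) > 0) paste(edges$from, edges$to, w, sep = "\t"))
    writeLines(out, path)
  } else {
    g <- as_igraph(network)
    if (!"weight" %in% igraph::edge_attr_names(g))
      igraph::E(g)$weight <- rep(1, igraph::ecount(g))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a cell-type network from a TSV written by [write_network()]
#'
#' @param path TSV with columns geneA, geneB, weight.
#' @param cell_type,parent labels attached to the resulting network.
#' @return a [ct_network].
#' @export
read_network <- function(path, cell_type = basename(path), parent = NA_character_) {
  ref <- read_edge_list(path, has_weight = TRUE, name = cell_type)
  ct_network(ref$edges, cell_type = cell_type, parent = parent)
}
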