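# Pairwise network similarity and multi-network intersection.
#
# Two similarity metrics: shared-edge similarity (Spearman correlation of
# the weights of edges present in both networks' shared-node subgraphs) and
# topology similarity (Spearman correlation of transformed topological
# specificity over shared nodes). Insufficient overlap yields NA, never 0 —
# a correlation of 0 is a meaningful value.

shared_edge_table <- function(a, b) {
  shared_nodes <- intersect(network_nodes(a), network_nodes(b))
  ea <- network_edges(a)
  eb <- network_edges(b)
  ea <- ea[ea$from %in% shared_nodes & ea$to %in% shared_nodes, ]
  eb <- eb[eb$from %in% shared_nodes & eb$to %in% shared_nodes, ]
  common <- intersect(edge_key(ea), edge_key(eb))
  list(
    shared_nodes = shared_nodes,
    wa = ea$weight[match(common, edge_key(ea))],
    wb = eb$weight[match(common, edge_key(eb))],
    n_shared_edges = length(common)
  )
}

#' Shared-edge similarity of two networks
#'
#' Spearman correlation between the weights the two networks assign to the
#' edges present in both subgraphs induced by their shared nodes.
#'
#' @param a,b [ct_network]s.
#' @return Spearman rho, or `NA` when fewer than 3 edges are shared.
#' @export
shared_edge_similarity <- function(a, b) {
  s <- shared_edge_table(a, b)
  if (s$n_shared_edges < 3) return(NA_real_)
  cor(s$wa, s$wb, method = "spearman")
}

#' Topology similarity of two networks
#'
#' Spearman correlation of transformed topological specificity
#' (`topS_transf`) over the networks' shared nodes, each score vector
#' computed on its own network.
#'
#' @param a,b [ct_network]s.
#' @param scores_a,scores_b `topology_scores` for `a` and `b`; computed with
#'   [topological_specificity()] defaults when omitted.
#' @return Spearman rho, or `NA` when fewer than 3 nodes are shared.
#' @export
topology_similarity <- function(a, b, scores_a = NULL, scores_b = NULL) {
  scores_a <- scores_a %||% topological_specificity(a)
  scores_b <- scores_b %||% topological_specificity(b)
  shared <- intersect(network_nodes(a), network_nodes(b))
  shared <- intersect(shared, intersect(scores_a$gene, scores_b$gene))
  if (length(shared) < 3) return(NA_real_)
  cor(scores_a$topS_transf[match(shared, scores_a$gene)],
      scores_b$topS_transf[match(shared, scores_b$gene)],
      method = "spearman")
}

#' Shared and unique node/edge accounting for two networks
#'
#' The unique-to-shared ratio is `(|A \ B| + |B \ A|) / |A intersect B|`,
#' computed separately for nodes and edges; an empty intersection yields
#' `NA`.
#'
#' @param a,b [ct_network]s.
#' @return one-row tibble with counts and ratios.
#' @export
shared_unique_counts <- function(a, b) {
  na_ <- network_nodes(a); nb_ <- network_nodes(b)
  ka <- edge_key(network_edges(a)); kb <- edge_key(network_edges(b))
  sn <- length(intersect(na_, nb_))
  se <- length(intersect(ka, kb))
  un <- length(setdiff(na_, nb_)) + length(setdiff(nb_, na_))
  ue <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  tibble(
    network_a = if (inherits(a, "ct_network")) a$cell_type else "a",
    network_b = if (inherits(b, "ct_network")) b$cell_type else "b",
    n_shared_nodes = sn,
    n_shared_edges = se,
    unique_to_shared_node_ratio = if (sn > 0) un / sn else NA_real_,
    unique_to_shared_edge_ratio = if (se > 0) ue / se else NA_real_
  )
}

#' Full pairwise comparison of two networks
#'
#' @inheritParams topology_similarity
#' @return one-row tibble combining [shared_unique_counts()],
#'   [shared_edge_similarity()] and [topology_similarity()].
#' @export
compare_networks <- function(a, b, scores_a = NULL, scores_b = NULL) {
  out <- shared_unique_counts(a, b)
  out$edge_similarity <- shared_edge_similarity(a, b)
  out$topology_similarity <- topology_similarity(a, b, scores_a, scores_b)
  out
}

#' Pairwise similarity over a panel of networks
#'
#' @param networks named list of [ct_network]s.
#' @param scores optional named list of matching `topology_scores`; computed
#'   on demand otherwise.
#' @return long tibble with one row per unordered pair.
#' @export
similarity_panel <- function(networks, scores = NULL) {
  stopifnot(length(networks) >= 2, !is.null(names(networks)))
  scores <- scores %||% lapply(networks, topological_specificity)
  pairs <- combn(names(networks), 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    out <- compare_networks(networks[[p[1]]], networks[[p[2]]],
                            scores[[p[1]]], scores[[p[2]]])
    out$network_a <- p[1]
    out$network_b <- p[2]
    out
  })
  bind_rows(rows)
}

#' Intersection of several networks
#'
#' Keeps the edges present in every input network; the intersection weight
#' is the mean (default) or the minimum of the input weights. The node set
#' is restricted to the retained edges' endpoints.
#'
#' @param networks list of at least two [ct_network]s.
#' @param weight_rule `"mean"` or `"min"`.
#' @return a [ct_network] labeled with the parent networks.
#' @export
network_intersection <- function(networks, weight_rule = c("mean", "min")) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(length(networks) >= 2)
  keys <- lapply(networks, function(n) edge_key(network_edges(n)))
  common <- Reduce(intersect, keys)
  label <- paste(vapply(networks, function(n)
    if (inherits(n, "ct_network")) n$cell_type else "network", ""),
    collapse = "&")
  if (length(common) == 0) {
    warn("network intersection is empty")
    return(ct_network(NULL, cell_type = label))
  }
  wmat <- vapply(seq_along(networks), function(i) {
    e <- network_edges(networks[[i]])
    e$weight[match(common, keys[[i]])]
  }, numeric(length(common)))
  wmat <- matrix(wmat, nrow = length(common))
  w <- if (weight_rule == "mean") rowMeans(wmat) else
    apply(wmat, 1, min)
  ft <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  ct_network(tibble(from = ft[, 1], to = ft[, 2], weight = w),
             cell_type = label,
             parent = paste(vapply(networks, function(n)
               if (inherits(n, "ct_network")) n$parent %||% NA_character_
               else n$name, ""), collapse = "&"))
}
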