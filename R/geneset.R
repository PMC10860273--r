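# Gene-set statistics on cell-type networks: local-network extraction,
# hypergeometric enrichment with BH correction, within-group connectivity
# with its random-subsampling permutation null, scaled connectivity across
# cell types, and hub/neighbor rankings.

#' Local network around a query gene
#'
#' Induced subgraph on all genes within graph distance `radius` of the
#' query, weights inherited.
#'
#' @param network a [ct_network].
#' @param gene query gene symbol; if absent an error lists the nearest
#'   symbol matches.
#' @param radius neighborhood radius (>= 0).
#' @return a [ct_network].
#' @export
local_network <- function(network, gene, radius = 1L) {
  nodes <- network_nodes(network)
  if (!gene %in% nodes) {
    near <- agrep(gene, nodes, max.distance = 0.3, value = TRUE)
    abort(paste0("gene '", gene, "' not in network",
                 if (length(near) > 0)
                   paste0("; nearest matches: ",
                          paste(head(near, 5), collapse = ", "))))
  }
  g <- as_igraph(network)
  keep <- igraph::ego(g, order = radius, nodes = gene)[[1]]$name
  e <- network_edges(network)
  e <- e[e$from %in% keep & e$to %in% keep, ]
  ct_network(e, cell_type = network$cell_type, parent = network$parent,
             nodes = keep)
}

#' Hypergeometric enrichment of a query gene list against gene sets
#'
#' For each set, tests over-representation of the query among the set's
#' members within a fixed gene universe with the upper-tail hypergeometric
#' probability `P(X >= k)`, then BH-adjusts across the tested sets. Query
#' genes outside the universe are dropped with a warning; sets are
#' intersected with the universe.
#'
#' @param sets gene-set tibble (`set`, `description`, `genes`), e.g. from
#'   [read_gmt()].
#' @param query character vector of query genes.
#' @param universe character vector of background genes. A natural choice is
#'   the node set of the network the query came from.
#' @return tibble sorted by p: `set`, `overlap` (k), `set_size_in_universe`
#'   (K), `query_size` (n), `universe_size` (N), `p`, `q`.
#' @export
hypergeometric_enrichment <- function(sets, query, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) outside the universe dropped"))
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  rows <- purrr::map2_dfr(sets$set, sets$genes, function(nm, g) {
    g <- intersect(g, universe)
    K <- length(g)
    k <- length(intersect(g, query))
    p <- if (K == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = nm, overlap = k, set_size_in_universe = K,
           query_size = n, universe_size = N, p = p)
  })
  rows$q <- p.adjust(rows$p, method = "BH")
  arrange(rows, .data$p, .data$set)
}

connectivity_denominator <- function(n_members, normalization) {
  switch(normalization,
         per_gene = n_members,
         sum = 1,
         per_pair = n_members * (n_members - 1) / 2)
}

#' Within-group connectivity of a gene set in a network
#'
#' The total weight of the network edges with both endpoints in the set,
#' normalized (by default) by the number of set members present in the
#' network, so sets with different network coverage stay comparable. Members
#' absent from the network are excluded entirely.
#'
#' @param network a [ct_network].
#' @param genes character vector of set members.
#' @param normalization `"per_gene"` (default), `"sum"`, or `"per_pair"`.
#' @return connectivity value, or `NA` when fewer than 2 members are in the
#'   network.
#' @export
within_group_connectivity <- function(network, genes,
                                      normalization = c("per_gene", "sum",
                                                        "per_pair")) {
  normalization <- match.arg(normalization)
  members <- intersect(unique(genes), network_nodes(network))
  if (length(members) < 2) return(NA_real_)
  e <- network_edges(network)
  internal <- e$from %in% members & e$to %in% members
  sum(e$weight[internal]) / connectivity_denominator(length(members),
                                                     normalization)
}

#' Permutation test for gene-set connectivity
#'
#' Builds the null by repeatedly drawing uniform random gene sets of the
#' same size (`|S intersect V|`) from the network's nodes and recomputing
#' connectivity. The empirical p-value uses the add-one correction
#' `p = (1 + #{null >= observed}) / (1 + n_permutations)`, so it is never 0.
#'
#' @inheritParams within_group_connectivity
#' @param n_permutations number of null sets (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param set_name optional label carried into the result.
#' @return one-row tibble: `set_name`, `cell_type`, `n_in_network`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `empirical_p`,
#'   `n_permutations`. `NA`s when fewer than 2 members are in the network.
#' @export
connectivity_permutation_test <- function(network, genes,
                                          n_permutations = 1000L, seed = 1L,
                                          normalization = c("per_gene", "sum",
                                                            "per_pair"),
                                          set_name = NA_character_) {
  normalization <- match.arg(normalization)
  if (n_permutations < 100) abort("n_permutations must be >= 100")
  nodes <- network_nodes(network)
  members <- intersect(unique(genes), nodes)
  m <- length(members)
  ct_label <- if (inherits(network, "ct_network")) network$cell_type else
    NA_character_
  if (m < 2) {
    return(tibble(set_name = set_name, cell_type = ct_label,
                  n_in_network = m, observed = NA_real_,
                  null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
                  empirical_p = NA_real_,
                  n_permutations = as.integer(n_permutations)))
  }
  observed <- within_group_connectivity(network, members, normalization)
  e <- network_edges(network)
  from_i <- match(e$from, nodes)
  to_i <- match(e$to, nodes)
  denom <- connectivity_denominator(m, normalization)
  null_stats <- local_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      inset <- logical(length(nodes))
      inset[sample.int(length(nodes), m)] <- TRUE
      sum(e$weight[inset[from_i] & inset[to_i]]) / denom
    }, 0)
  })
  null_mean <- mean(null_stats)
  null_sd <- sd(null_stats)
  tibble(
    set_name = set_name, cell_type = ct_label, n_in_network = m,
    observed = observed, null_mean = null_mean, null_sd = null_sd,
    z = if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_,
    empirical_p = (1 + sum(null_stats >= observed)) / (1 + n_permutations),
    n_permutations = as.integer(n_permutations)
  )
}

#' Scaled connectivity of a gene set across cell types
#'
#' Runs the connectivity permutation test in every cell type's network,
#' takes the permutation z-score per cell type, and centers/scales the z
#' vector across cell types to mean 0 and sd 1 — the deconvolution score
#' that assigns a gene signature to cell types.
#'
#' @param networks named list of [ct_network]s (>= 2 with defined
#'   connectivity).
#' @inheritParams connectivity_permutation_test
#' @return tibble with one row per cell type: the permutation-test columns
#'   plus `scaled`.
#' @export
scaled_connectivity <- function(networks, genes, n_permutations = 1000L,
                                seed = 1L,
                                normalization = c("per_gene", "sum",
                                                  "per_pair"),
                                set_name = NA_character_) {
  normalization <- match.arg(normalization)
  stopifnot(!is.null(names(networks)))
  rows <- purrr::imap_dfr(networks, function(net, nm) {
    out <- connectivity_permutation_test(net, genes, n_permutations,
                                         seed = seed,
                                         normalization = normalization,
                                         set_name = set_name)
    out$cell_type <- nm
    out
  })
  defined <- is.finite(rows$z)
  if (sum(defined) < 2)
    abort("scaled connectivity needs >= 2 cell types with defined z")
  z <- rows$z[defined]
  rows$scaled <- NA_real_
  # identical profiles across cell types carry no deconvolution signal:
  # the scaled score is exactly 0 rather than 0/0
  rows$scaled[defined] <- if (sd(z) > 0) (z - mean(z)) / sd(z) else 0
  rows
}

#' Hub and neighbor rankings for a gene set
#'
#' Ranks set members by their within-network strength (weighted degree
#' centrality) and non-member neighbors by the total weight of their edges
#' to set members. Ties are broken by gene symbol.
#'
#' @param network a [ct_network].
#' @param genes character vector of set members.
#' @param top_n truncate both rankings to this many rows (default all).
#' @return list of two tibbles: `members` (`gene`, `strength`, `rank`) and
#'   `neighbors` (`gene`, `strength_to_set`, `rank`).
#' @export
hub_rankings <- function(network, genes, top_n = Inf) {
  members <- intersect(unique(genes), network_nodes(network))
  if (length(members) == 0) abort("gene set does not intersect the network")
  s <- strength_vector(network)
  member_order <- rank_genes(s[members])
  members_tbl <- tibble(gene = member_order,
                        strength = unname(s[member_order]),
                        rank = seq_along(member_order))
  e <- network_edges(network)
  to_set <- c(
    setNames(e$weight[e$to %in% members], e$from[e$to %in% members]),
    setNames(e$weight[e$from %in% members], e$to[e$from %in% members])
  )
  to_set <- to_set[!names(to_set) %in% members]
  if (length(to_set) > 0) {
    agg <- tapply(to_set, names(to_set), sum)
    nb_order <- rank_genes(setNames(as.numeric(agg), names(agg)))
    neighbors_tbl <- tibble(gene = nb_order,
                            strength_to_set = as.numeric(agg[nb_order]),
                            rank = seq_along(nb_order))
  } else {
    neighbors_tbl <- tibble(gene = character(), strength_to_set = numeric(),
                            rank = integer())
  }
  list(members = head(members_tbl, top_n),
       neighbors = head(neighbors_tbl, top_n))
}
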