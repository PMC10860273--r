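# Node-level topology statistics on a cell-type network: neighborhood
# strength, topological specificity (topS) against an edge-reshuffle null,
# its logistic transform, and the topS-vs-tranS comparison statistics.

#' Neighborhood strength of every node
#'
#' The total strength of a gene's local neighborhood: the sum of the weights
#' of its incident edges. Isolated nodes have strength 0.
#'
#' @param network a [ct_network] (or weighted [interactome]).
#' @return tibble with columns `gene`, `strength`, covering all nodes.
#' @export
neighborhood_strength <- function(network) {
  w <- strength_vector(network)
  tibble(gene = names(w), strength = unname(w))
}

strength_vector <- function(network) {
  nodes <- network_nodes(network)
  e <- network_edges(network)
  w <- if ("weight" %in% names(e)) e$weight else rep(1, nrow(e))
  s <- setNames(numeric(length(nodes)), nodes)
  if (nrow(e) > 0) {
    inc <- tapply(c(w, w), c(e$from, e$to), sum)
    s[names(inc)] <- inc
  }
  s
}

#' Topological specificity (topS) with an edge-reshuffle null
#'
#' The null model fixes the network topology and uniformly reshuffles the
#' multiset of edge weights over the edge set; `topS(i)` is the z-score of
#' node `i`'s neighborhood strength against that null:
#' `topS = (w - mu_R) / sigma_R`. Two estimators are provided and agree:
#' * `"monte_carlo"`: `mu_R`, `sigma_R` from `n_shuffles` random weight
#'   permutations;
#' * `"closed_form"`: the exact moments of sampling `d_i` of the `M` edge
#'   weights without replacement, `mu_R = d_i * wbar`,
#'   `sigma_R^2 = d_i * s_w^2 * (M - d_i) / (M - 1)` with `wbar`, `s_w^2` the
#'   population mean/variance of the weights.
#'
#' Degenerate nulls (`sigma_R = 0`, e.g. all weights equal) give `topS = 0`.
#' The logistic transform `topS_transf = 1 / (1 + exp(-topS))` is attached
#' for cross-network comparison.
#'
#' @param network a [ct_network].
#' @param mode `"closed_form"` (default) or `"monte_carlo"`.
#' @param n_shuffles reshuffles for Monte-Carlo mode (>= 100).
#' @param seed RNG seed for Monte-Carlo mode.
#' @return a `topology_scores` tibble: `gene`, `degree`, `strength`, `mu_R`,
#'   `sigma_R`, `topS`, `topS_transf`; attribute `mode` records the
#'   estimator.
#' @export
topological_specificity <- function(network, mode = c("closed_form",
                                                      "monte_carlo"),
                                    n_shuffles = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  nodes <- network_nodes(network)
  e <- network_edges(network)
  M <- nrow(e)
  w_obs <- strength_vector(network)
  deg <- setNames(numeric(length(nodes)), nodes)
  if (M > 0) {
    d <- table(c(e$from, e$to))
    deg[names(d)] <- as.numeric(d)
  }
  wts <- e$weight
  if (mode == "closed_form") {
    if (M < 2) {
      warn("fewer than 2 edges: closed-form null variance undefined; topS = 0")
      mu <- deg * if (M == 1) wts else 0
      sigma <- deg * 0
    } else {
      wbar <- mean(wts)
      s2 <- mean((wts - wbar)^2)          # population variance
      mu <- deg * wbar
      sigma <- sqrt(deg * s2 * (M - deg) / (M - 1))
    }
    n_shuffles_used <- NA_integer_
  } else {
    if (n_shuffles < 100) abort("monte_carlo requires n_shuffles >= 100")
    if (M < 1) abort("monte_carlo requires at least one edge")
    idx <- match(c(e$from, e$to), nodes)
    B <- sparseMatrix(i = idx, j = rep(seq_len(M), 2L), x = 1,
                      dims = c(length(nodes), M))
    perm <- local_seed(seed, {
      matrix(wts[vapply(seq_len(n_shuffles), function(i) sample.int(M),
                        integer(M))], nrow = M)
    })
    S <- as.matrix(B %*% perm)
    mu <- setNames(rowMeans(S), nodes)
    sigma <- setNames(sqrt(rowMeans((S - mu)^2)), nodes)
    n_shuffles_used <- as.integer(n_shuffles)
  }
  topS <- ifelse(sigma > 0, (w_obs - mu) / sigma, 0)
  out <- tibble(
    gene = nodes,
    degree = unname(deg),
    strength = unname(w_obs),
    mu_R = unname(mu),
    sigma_R = unname(sigma),
    topS = unname(topS),
    topS_transf = 1 / (1 + exp(-unname(topS)))
  )
  structure(out, class = c("topology_scores", class(out)),
            mode = mode, n_shuffles = n_shuffles_used,
            cell_type = if (inherits(network, "ct_network"))
              network$cell_type else NA_character_)
}

#' @method glance topology_scores
#' @export
glance.topology_scores <- function(x, ...) {
  tibble(
    cell_type = attr(x, "cell_type"),
    mode = attr(x, "mode"),
    n_shuffles = attr(x, "n_shuffles"),
    n_genes = nrow(x),
    mean_topS = mean(x$topS),
    max_topS = max(x$topS)
  )
}

#' Jaccard index of two top-k gene lists
#'
#' @param ranking_a,ranking_b character vectors of genes ordered best-first
#'   (e.g. from [rank_genes()], which breaks ties by symbol).
#' @param k how many top genes to compare (0 < k <= both lengths).
#' @return Jaccard index in `[0, 1]`.
#' @export
top_k_jaccard <- function(ranking_a, ranking_b, k) {
  if (k <= 0) abort("k must be positive")
  if (k > length(ranking_a) || k > length(ranking_b))
    abort("k exceeds a ranking length")
  a <- ranking_a[seq_len(k)]
  b <- ranking_b[seq_len(k)]
  length(intersect(a, b)) / length(union(a, b))
}

#' Log2 fold change between topS and tranS percentile ranks
#'
#' Ranks both scores ascending over the common gene universe, converts to
#' percentile ranks `PR = rank / G` (so the most specific gene has PR = 1),
#' and reports `log2(PR_topS / PR_tranS)` — positive for genes whose network
#' influence exceeds what their expression specificity alone suggests.
#' Genes missing from either mapping are excluded with a warning.
#'
#' @param topS,tranS named numeric vectors over (mostly) the same genes.
#' @return tibble with `gene`, `pr_topS`, `pr_tranS`, `log2fc`, sorted by
#'   decreasing `log2fc`.
#' @export
percentile_rank_log2fc <- function(topS, tranS) {
  common <- intersect(names(topS), names(tranS))
  dropped <- length(union(names(topS), names(tranS))) - length(common)
  if (dropped > 0)
    warn(paste0(dropped, " gene(s) missing from one mapping were excluded"))
  if (length(common) == 0) abort("no genes shared between the two mappings")
  a <- topS[common]
  b <- tranS[common]
  G <- length(common)
  pr_a <- rank(a, ties.method = "average") / G
  pr_b <- rank(b, ties.method = "average") / G
  out <- tibble(gene = common, pr_topS = unname(pr_a),
                pr_tranS = unname(pr_b),
                log2fc = log2(unname(pr_a) / unname(pr_b)))
  arrange(out, desc(.data$log2fc), .data$gene)
}
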