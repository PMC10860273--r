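# Random walk with restart gene prioritization, degree-preserving rewired
# null networks, and network performance scoring via gene-set recovery AUPRC.

# Column-normalized weighted adjacency of a network. Isolated nodes receive
# a unit self-loop purely to keep the matrix column-stochastic; no seed
# probability can ever flow to them.
column_normalized_adjacency <- function(network) {
  nodes <- network_nodes(network)
  e <- network_edges(network)
  n <- length(nodes)
  if (nrow(e) > 0) {
    i <- match(c(e$from, e$to), nodes)
    j <- match(c(e$to, e$from), nodes)
    A <- sparseMatrix(i = i, j = j, x = rep(e$weight, 2), dims = c(n, n))
  } else {
    A <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                      dims = c(n, n))
  }
  colsum <- colSums(A)
  isolated <- which(colsum == 0)
  if (length(isolated) > 0) {
    A <- A + sparseMatrix(i = isolated, j = isolated,
                          x = rep(1, length(isolated)), dims = c(n, n))
    colsum[isolated] <- 1
  }
  W <- A %*% Diagonal(x = 1 / colsum)
  dimnames(W) <- list(nodes, nodes)
  W
}

#' Random walk with restart
#'
#' Iterates `p_{t+1} = (1 - gamma) W p_t + gamma p_0` until the L1 difference
#' between successive vectors falls below `tol`. `W` is the column-normalized
#' weighted adjacency matrix of the network, and `p_0` is uniform over the
#' seed genes found in the network, zero elsewhere.
#'
#' @param network a [ct_network] (or weighted [interactome]).
#' @param seeds character vector of seed genes; at least one must be in the
#'   network.
#' @param gamma restart probability in (0, 1] (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return an `rwr_result` with the stationary vector `p_star` (sums to 1),
#'   the seeds used, `gamma` and the iteration count.
#' @export
rwr <- function(network, seeds, gamma = 0.5, tol = 1e-10, max_iter = 1e5) {
  if (gamma <= 0 || gamma > 1) abort("gamma must be in (0, 1]")
  nodes <- network_nodes(network)
  seeds_in <- intersect(unique(seeds), nodes)
  if (length(seeds_in) == 0) abort("no seed gene is present in the network")
  W <- column_normalized_adjacency(network)
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[seeds_in] <- 1 / length(seeds_in)
  p <- p0
  iter <- 0L
  repeat {
    p_new <- as.numeric((1 - gamma) * (W %*% p) + gamma * p0)
    delta <- sum(abs(p_new - p))
    p <- setNames(p_new, nodes)
    iter <- iter + 1L
    if (delta < tol) break
    if (iter >= max_iter)
      abort(paste0("RWR did not converge in ", max_iter,
                   " iterations (L1 residual ", signif(delta, 3), ")"))
  }
  structure(
    list(p_star = p, p0 = p0, seeds = seeds_in, gamma = gamma, tol = tol,
         iterations = iter,
         network = if (inherits(network, "ct_network")) network$cell_type
           else network$name),
    class = "rwr_result"
  )
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("<rwr_result> ", length(x$p_star), " genes, ", length(x$seeds),
      " seeds, gamma = ", x$gamma, ", converged in ", x$iterations,
      " iterations\n", sep = "")
  invisible(x)
}

#' @describeIn rwr per-gene tibble (`gene`, `p_star`, `is_seed`), sorted by
#'   descending stationary probability with ties broken by symbol.
#' @param x an `rwr_result`.
#' @param ... unused.
#' @method tidy rwr_result
#' @export
tidy.rwr_result <- function(x, ...) {
  out <- tibble(gene = names(x$p_star), p_star = unname(x$p_star),
                is_seed = names(x$p_star) %in% x$seeds)
  arrange(out, desc(.data$p_star), .data$gene)
}

#' @method glance rwr_result
#' @export
glance.rwr_result <- function(x, ...) {
  tibble(network = x$network, n_genes = length(x$p_star),
         n_seeds = length(x$seeds), gamma = x$gamma, tol = x$tol,
         iterations = x$iterations, total_probability = sum(x$p_star))
}

#' Prioritize candidate genes from seed genes
#'
#' Runs [rwr()] and returns the non-seed genes ranked by descending
#' stationary probability (ties broken by symbol). Seed genes are reported
#' in the `seeds` attribute rather than the ranking.
#'
#' @inheritParams rwr
#' @return tibble (`gene`, `p_star`, `rank`) of candidates.
#' @export
prioritize <- function(network, seeds, gamma = 0.5, tol = 1e-10,
                       max_iter = 1e5) {
  res <- rwr(network, seeds, gamma = gamma, tol = tol, max_iter = max_iter)
  out <- filter(tidy(res), !.data$is_seed)
  out <- select(mutate(out, rank = row_number()), -"is_seed")
  attr(out, "seeds") <- res$seeds
  out
}

#' Degree-matched rewired null network
#'
#' Rewires the network with repeated double-edge swaps that preserve every
#' node's degree exactly (no self-loops or multi-edges are created), then
#' reassigns the original multiset of edge weights to the new edge set by
#' random permutation.
#'
#' @param network a [ct_network] with >= 2 edges.
#' @param n_swap_multiplier attempted swaps as a multiple of the edge count.
#' @param seed RNG seed.
#' @return a rewired [ct_network].
#' @export
degree_preserving_rewire <- function(network, n_swap_multiplier = 10L,
                                     seed = 1L) {
  e <- network_edges(network)
  if (nrow(e) < 2) abort("rewiring requires at least 2 edges")
  g <- as_igraph(network)
  local_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = n_swap_multiplier * nrow(e)))
    el <- igraph::as_data_frame(g2, what = "edges")
    new_edges <- tibble(from = el$from, to = el$to,
                        weight = sample(e$weight))
    ct_network(new_edges,
               cell_type = paste0(network$cell_type, "_rewired"),
               parent = network$parent, nodes = network_nodes(network))
  })
}

#' Area under the precision-recall curve
#'
#' Average-precision estimator: mean over positives of the precision at each
#' positive's rank, with ties broken deterministically by item name.
#'
#' @param scores named numeric vector (larger = ranked higher).
#' @param positives character vector of positive item names.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, positives) {
  stopifnot(!is.null(names(scores)))
  ord <- order(-scores, names(scores))
  lab <- names(scores)[ord] %in% positives
  if (!any(lab)) abort("no positive item among the scored items")
  hits <- cumsum(lab)
  precision_at_pos <- hits[lab] / which(lab)
  mean(precision_at_pos)
}

# Fixed seed/hold-out splits reused across a network and its nulls.
make_recovery_splits <- function(members, split_fraction, repeats, seed) {
  m <- length(members)
  n_seed <- max(2L, min(m - 2L, round(split_fraction * m)))
  local_seed(seed, {
    lapply(seq_len(repeats), function(i) {
      idx <- sample.int(m, n_seed)
      list(seeds = members[idx], held_out = members[-idx])
    })
  })
}

recovery_auprc_with_splits <- function(network, splits, gamma, tol) {
  vals <- vapply(splits, function(sp) {
    res <- rwr(network, sp$seeds, gamma = gamma, tol = tol)
    cand <- res$p_star[!names(res$p_star) %in% res$seeds]
    pos <- intersect(sp$held_out, names(cand))
    if (length(pos) == 0) return(NA_real_)
    auprc(cand, pos)
  }, 0)
  mean(vals, na.rm = TRUE)
}

#' Gene-set recovery AUPRC of a network
#'
#' Repeatedly splits the set's network members into seed genes
#' (`split_fraction`) and held-out positives, propagates from the seeds with
#' [rwr()], and scores how well the held-out members are recovered among all
#' non-seed network genes by [auprc()]. Returns the mean over repeats.
#'
#' @param network a [ct_network].
#' @param genes gene-set members; at least 4 must be in the network.
#' @param split_fraction fraction used as seeds per repeat.
#' @param repeats number of random splits.
#' @param gamma,tol RWR parameters.
#' @param seed RNG seed (drives the splits).
#' @return mean AUPRC over repeats.
#' @export
geneset_recovery_auprc <- function(network, genes, split_fraction = 0.5,
                                   repeats = 10L, gamma = 0.5, tol = 1e-10,
                                   seed = 1L) {
  members <- intersect(unique(genes), network_nodes(network))
  if (length(members) < 4)
    abort("recovery requires at least 4 set members in the network")
  splits <- make_recovery_splits(members, split_fraction, repeats, seed)
  recovery_auprc_with_splits(network, splits, gamma, tol)
}

#' Network performance and performance gain versus degree-matched nulls
#'
#' Evaluates the network's gene-set recovery AUPRC against `n_null`
#' independent degree-preserving rewirings, using the same seed/hold-out
#' splits for the true network and every null. Performance is the robust
#' z-score of the true AUPRC against the null ensemble,
#' `(AUPRC - median(null)) / (1.4826 * MAD(null))`; performance gain is
#' `(AUPRC - median(null)) / median(null)`.
#'
#' @inheritParams geneset_recovery_auprc
#' @param n_null number of rewired null networks (>= 10).
#' @param n_swap_multiplier swaps per rewiring, as a multiple of the edge
#'   count.
#' @return a `network_performance` object; see [glance()] for the one-row
#'   summary.
#' @export
performance_and_gain <- function(network, genes, n_null = 20L,
                                 split_fraction = 0.5, repeats = 10L,
                                 gamma = 0.5, tol = 1e-10,
                                 n_swap_multiplier = 10L, seed = 1L) {
  if (n_null < 10) abort("n_null must be >= 10")
  members <- intersect(unique(genes), network_nodes(network))
  if (length(members) < 4)
    abort("recovery requires at least 4 set members in the network")
  splits <- make_recovery_splits(members, split_fraction, repeats, seed)
  true_auprc <- recovery_auprc_with_splits(network, splits, gamma, tol)
  null_auprcs <- vapply(seq_len(n_null), function(i) {
    null_net <- degree_preserving_rewire(network, n_swap_multiplier,
                                         seed = seed + i)
    recovery_auprc_with_splits(null_net, splits, gamma, tol)
  }, 0)
  med <- median(null_auprcs)
  mad_null <- mad(null_auprcs)   # 1.4826 * median absolute deviation
  structure(
    list(
      auprc = true_auprc,
      null_auprcs = null_auprcs,
      performance = if (mad_null > 0) (true_auprc - med) / mad_null else
        NA_real_,
      gain = if (med > 0) (true_auprc - med) / med else NA_real_,
      n_null = as.integer(n_null),
      recovery_params = list(split_fraction = split_fraction,
                             repeats = repeats, gamma = gamma, tol = tol,
                             seed = as.integer(seed)),
      network = if (inherits(network, "ct_network")) network$cell_type else
        network$name
    ),
    class = "network_performance"
  )
}

#' @export
print.network_performance <- function(x, ...) {
  cat("<network_performance> ", x$network, ": AUPRC = ",
      signif(x$auprc, 4), ", null median = ",
      signif(median(x$null_auprcs), 4), ", performance = ",
      signif(x$performance, 4), ", gain = ", signif(x$gain, 4), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn performance_and_gain null ensemble as a tibble.
#' @param x a `network_performance`.
#' @param ... unused.
#' @method tidy network_performance
#' @export
tidy.network_performance <- function(x, ...) {
  tibble(null_index = seq_along(x$null_auprcs),
         null_auprc = x$null_auprcs)
}

#' @method glance network_performance
#' @export
glance.network_performance <- function(x, ...) {
  tibble(network = x$network, auprc = x$auprc,
         null_median = median(x$null_auprcs),
         null_mad = mad(x$null_auprcs),
         performance = x$performance, gain = x$gain, n_null = x$n_null)
}
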