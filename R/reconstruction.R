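# Reference-guided reconstruction of cell-type-specific networks.
#
# Gene specificity per cell type is a Welch-style contrast of normalized
# expression (cell type vs all other cells), mapped to normal quantiles by a
# rank-inverse-normal transform. A reference edge is retained for a cell
# type when the Stouffer combination of its endpoints' z-scores is
# significantly positive after BH correction across all tested edges.
# NOTE: the edge statistic here is an analytic Stouffer combiner, a
# documented simplification of the subsampling ensembles some reference-
# guided implementations use; the combiner is a pluggable argument.

# log1p of counts-per-10k, computed sparsely (zeros stay zero).
normalize_cp10k <- function(counts) {
  depth <- rowSums(counts)
  depth[depth == 0] <- 1
  x <- Diagonal(x = 1e4 / depth) %*% counts
  x@x <- log1p(x@x)
  x
}

# Welch-style specificity on an already-normalized cells x genes matrix.
# groups: factor/character per cell. Returns list of gene x group matrices.
welch_specificity <- function(x, groups, cap = 50) {
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  if (length(labs) < 2) abort("at least two cell types are required")
  n_cells <- table(groups)[labs]
  if (any(n_cells < 2))
    abort(paste0("cell type with fewer than 2 cells: ",
                 paste(labs[n_cells < 2], collapse = ", ")))
  ind <- sparseMatrix(i = seq_along(groups),
                      j = match(groups, labs),
                      x = 1, dims = c(length(groups), length(labs)))
  s1 <- as.matrix(crossprod(x, ind))       # genes x groups sums
  x2 <- x
  x2@x <- x2@x^2
  s2 <- as.matrix(crossprod(x2, ind))      # genes x groups sums of squares
  n <- as.numeric(n_cells)
  N <- length(groups)
  tot1 <- rowSums(s1)
  tot2 <- rowSums(s2)
  mean_in <- sweep(s1, 2, n, "/")
  var_in <- sweep(s2 - sweep(mean_in^2, 2, n, "*"), 2, n - 1, "/")
  n_out <- N - n
  mean_out <- sweep(tot1 - s1, 2, n_out, "/")
  var_out <- sweep((tot2 - s2) - sweep(mean_out^2, 2, n_out, "*"),
                   2, n_out - 1, "/")
  var_in <- pmax(var_in, 0)   # guard tiny negatives from cancellation
  var_out <- pmax(var_out, 0)
  num <- mean_in - mean_out
  den <- sqrt(sweep(var_in, 2, n, "/") + sweep(var_out, 2, n_out, "/"))
  tranS <- num / den
  degenerate <- den == 0
  tranS[degenerate] <- sign(num[degenerate]) * cap
  tranS[degenerate & num == 0] <- 0
  dimnames(tranS) <- list(rownames(s1), labs)
  list(tranS = tranS, mean_in = mean_in, mean_out = mean_out,
       var_in = var_in, var_out = var_out,
       n_in = setNames(as.integer(n), labs),
       n_out = setNames(as.integer(n_out), labs))
}

#' Rank-inverse-normal transform
#'
#' Maps scores to normal quantiles via `qnorm((r - 0.5) / G)` where `r` is
#' the 1-based rank (average rank for ties) and `G` the number of scores.
#' Monotone in the input; a single score maps to 0.
#'
#' @param scores finite numeric vector.
#' @return numeric vector of z-scores, names preserved.
#' @export
rank_inverse_normal <- function(scores) {
  if (any(!is.finite(scores))) abort("scores must be finite")
  r <- rank(scores, ties.method = "average")
  setNames(qnorm((r - 0.5) / length(scores)), names(scores))
}

#' Transcriptional specificity profile of an expression dataset
#'
#' Normalizes counts as log1p of counts-per-10,000 and, for each gene and
#' cell type, contrasts mean expression in the cell type against all other
#' cells with a Welch-style statistic
#' `tranS = (x_ct - x_else) / sqrt(s2_ct / n_ct + s2_else / n_else)`.
#' When both group variances are zero the statistic is 0 for equal means and
#' `sign(difference) * 50` otherwise. Within each cell type, tranS is mapped
#' to normal quantiles by [rank_inverse_normal()] (column `z`), the scale on
#' which edge significance is assessed.
#'
#' @param expr an [expression_dataset] with at least two cell types.
#' @return a `specificity_profile`: gene-by-cell-type matrices `tranS` and
#'   `z`, per-group means/variances/sizes, and `n_cells`.
#' @export
compute_transcriptional_specificity <- function(expr) {
  stopifnot(inherits(expr, "expression_dataset"))
  x <- normalize_cp10k(expr$counts)
  w <- welch_specificity(x, expr$meta$cell_type)
  z <- apply(w$tranS, 2, rank_inverse_normal)
  dimnames(z) <- dimnames(w$tranS)
  structure(
    list(tranS = w$tranS, z = z,
         n_cells = w$n_in,
         group_stats = w[c("mean_in", "mean_out", "var_in", "var_out",
                           "n_in", "n_out")]),
    class = "specificity_profile"
  )
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat("<specificity_profile> ", nrow(x$tranS), " genes x ", ncol(x$tranS),
      " cell types\n", sep = "")
  invisible(x)
}

#' @describeIn compute_transcriptional_specificity long tibble
#'   (gene, cell_type, tranS, z).
#' @param x a `specificity_profile`.
#' @param ... unused.
#' @method tidy specificity_profile
#' @export
tidy.specificity_profile <- function(x, ...) {
  out <- tibble(
    gene = rep(rownames(x$tranS), times = ncol(x$tranS)),
    cell_type = rep(colnames(x$tranS), each = nrow(x$tranS)),
    tranS = as.vector(x$tranS),
    z = as.vector(x$z)
  )
  arrange(out, .data$cell_type, .data$gene)
}

# Default edge combiner: Stouffer sum of endpoint z-scores.
stouffer_combiner <- function(z_i, z_j) (z_i + z_j) / sqrt(2)

#' Reconstruct one cell-type-specific network
#'
#' For every reference edge whose endpoints were both measured, combines the
#' endpoints' rank-inverse-normal specificity z-scores (default: Stouffer,
#' `z_ij = (z_i + z_j) / sqrt(2)`), converts to an upper-tail normal p-value,
#' BH-adjusts across all tested edges, and retains edges with
#' `q <= alpha_edge_q` and `z_ij > 0`. Retained edges carry `w = z_ij` as
#' interaction strength. Cell types with fewer than `cfg$min_cells` cells are
#' refused.
#'
#' @param reference an [interactome].
#' @param profile a `specificity_profile` from
#'   [compute_transcriptional_specificity()].
#' @param cell_type cell-type label present in the profile.
#' @param cfg a [run_config()].
#' @param combiner function of two z-score vectors returning the combined
#'   edge z-score (pluggable; defaults to the Stouffer sum).
#' @return a [ct_network] with edge columns `weight` and `q_value`.
#' @export
reconstruct_cell_type_network <- function(reference, profile, cell_type,
                                          cfg = run_config(),
                                          combiner = stouffer_combiner) {
  stopifnot(inherits(reference, "interactome"),
            inherits(profile, "specificity_profile"))
  if (!cell_type %in% colnames(profile$z))
    abort(paste0("unknown cell type: ", cell_type))
  n <- profile$n_cells[[cell_type]]
  if (n < cfg$min_cells)
    abort(paste0("cell type ", cell_type, " has ", n,
                 " cells; a minimum of ", cfg$min_cells, " is required"))
  z <- profile$z[, cell_type]
  measured <- names(z)
  e <- reference$edges
  e <- e[e$from %in% measured & e$to %in% measured, c("from", "to")]
  if (nrow(e) == 0) {
    return(ct_network(NULL, cell_type = cell_type, parent = reference$name))
  }
  z_edge <- combiner(z[e$from], z[e$to])
  p <- pnorm(z_edge, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  keep <- q <= cfg$alpha_edge_q & z_edge > 0
  ct_network(tibble(from = e$from, to = e$to,
                    weight = unname(z_edge), q_value = unname(q))[keep, ],
             cell_type = cell_type, parent = reference$name)
}

#' Dense cell-type propagation network
#'
#' The same reconstruction as [reconstruct_cell_type_network()] with the BH
#' filter released (`alpha_edge_q = 1`): every reference edge whose combined
#' specificity z-score is positive for the cell type is retained, weighted
#' by `z_ij`. The q <= alpha network is a sparse "specific core" suited to
#' topology and connectivity statistics; random-walk prioritization needs a
#' candidate pool at the scale of the interactome, which this dense variant
#' provides while still tilting edge weights toward the cell type.
#'
#' @inheritParams reconstruct_cell_type_network
#' @return a [ct_network] covering all positively-combined edges.
#' @export
propagation_network <- function(reference, profile, cell_type,
                                cfg = run_config(),
                                combiner = stouffer_combiner) {
  cfg$alpha_edge_q <- 1
  reconstruct_cell_type_network(reference, profile, cell_type, cfg, combiner)
}

#' Reconstruct networks for all eligible cell types
#'
#' Applies [reconstruct_cell_type_network()] to every cell type with at
#' least `cfg$min_cells` cells; skipped cell types are logged.
#'
#' @inheritParams reconstruct_cell_type_network
#' @return named list of [ct_network]s.
#' @export
reconstruct_networks <- function(reference, profile, cfg = run_config(),
                                 combiner = stouffer_combiner) {
  eligible <- names(profile$n_cells)[profile$n_cells >= cfg$min_cells]
  skipped <- setdiff(names(profile$n_cells), eligible)
  if (length(skipped) > 0)
    ct_log("reconstruct_networks: skipping ", length(skipped),
           " cell type(s) below min_cells: ", paste(skipped, collapse = ", "))
  setNames(
    lapply(eligible, function(ct)
      reconstruct_cell_type_network(reference, profile, ct, cfg, combiner)),
    eligible
  )
}
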