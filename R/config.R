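# Run configuration: the small set of tunable analysis parameters.

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' the BH q-value cutoff for retaining edges at reconstruction
#' (`alpha_edge_q`), the minimum number of cells a cell type needs before a
#' network is built for it (`min_cells`, default 100), permutation and null
#' network counts, and the random-walk restart probability (`rwr_gamma`,
#' default 0.5) and convergence tolerance (`rwr_tol`, default 1e-10).
#'
#' @param alpha_edge_q BH q-value threshold in (0, 1] for edge retention.
#' @param min_cells positive integer; cell types with fewer cells are skipped.
#' @param n_permutations positive integer; permutations for connectivity tests.
#' @param n_null_networks positive integer; rewired nulls for performance.
#' @param rwr_gamma restart probability in (0, 1].
#' @param rwr_tol positive convergence tolerance on the L1 step difference.
#' @param rng_seed integer seed used by stochastic stages.
#' @param connectivity_normalization how within-group connectivity is
#'   normalized: `"per_gene"` (sum of internal edge weights divided by the
#'   number of set members in the network), `"sum"`, or `"per_pair"`.
#' @return a `run_config` list.
#' @export
run_config <- function(alpha_edge_q = 0.05, min_cells = 100L,
                       n_permutations = 1000L, n_null_networks = 20L,
                       rwr_gamma = 0.5, rwr_tol = 1e-10, rng_seed = 1L,
                       connectivity_normalization = c("per_gene", "sum", "per_pair")) {
  connectivity_normalization <- match.arg(connectivity_normalization)
  check_scalar <- function(x, nm, lo, hi = Inf, int = FALSE,
                           lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      abort(paste0("`", nm, "` must be a finite numeric scalar"))
    if (x < lo || (lo_open && x <= lo) || x > hi)
      abort(paste0("`", nm, "` out of range"))
    if (int && x != round(x))
      abort(paste0("`", nm, "` must be an integer"))
  }
  check_scalar(alpha_edge_q, "alpha_edge_q", 0, 1, lo_open = TRUE)
  check_scalar(min_cells, "min_cells", 1, int = TRUE)
  check_scalar(n_permutations, "n_permutations", 1, int = TRUE)
  check_scalar(n_null_networks, "n_null_networks", 1, int = TRUE)
  check_scalar(rwr_gamma, "rwr_gamma", 0, 1, lo_open = TRUE)
  check_scalar(rwr_tol, "rwr_tol", 0, lo_open = TRUE)
  check_scalar(rng_seed, "rng_seed", -Inf, Inf, int = TRUE)
  structure(
    list(alpha_edge_q = alpha_edge_q, min_cells = as.integer(min_cells),
         n_permutations = as.integer(n_permutations),
         n_null_networks = as.integer(n_null_networks),
         rwr_gamma = rwr_gamma, rwr_tol = rwr_tol,
         rng_seed = as.integer(rng_seed),
         connectivity_normalization = connectivity_normalization),
    class = "run_config"
  )
}

#' Read a configuration from a flat key=value text file
#'
#' Unknown keys are rejected; values are validated by [run_config()].
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path path to the configuration file.
#' @param ... overrides applied after the file is read.
#' @return a `run_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, 1L) != 2L)
  if (length(bad) > 0)
    abort(paste0("malformed config line: ", lines[bad[1]]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  allowed <- names(formals(run_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0)
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  args <- setNames(as.list(vals), keys)
  args <- lapply(args, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}
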