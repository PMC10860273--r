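# Shared fixtures, built in code. Expensive simulated objects are memoized
# so several test files can reuse them within one run.

options(ctnet.quiet = TRUE)

.fixture_cache <- new.env(parent = emptyenv())

memoize_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small weighted network: a 6-node graph with distinct weights.
toy_network <- function() {
  ct_network(
    tibble::tibble(
      from = c("A", "A", "B", "B", "C", "D", "E"),
      to   = c("B", "C", "C", "D", "E", "E", "F"),
      weight = c(5, 1, 2, 4, 3, 2.5, 0.5)
    ),
    cell_type = "toy"
  )
}

# Random connected weighted network for property tests.
random_network <- function(n_nodes, mean_degree = 4, seed = 1,
                           cell_type = "rand") {
  ref <- generate_reference_network(n_nodes, mean_degree, seed = seed)
  e <- network_edges(ref)
  e$weight <- withr::with_seed(seed + 1, stats::rexp(nrow(e)) + 0.05)
  ct_network(e, cell_type = cell_type)
}

# Moderate end-to-end study reused across reconstruction/geneset tests.
small_study <- function() {
  memoize_fixture("small_study", function() {
    sim <- simulate_study(seed = 42, n_genes = 1500, mean_degree = 4,
                          cell_types = c(ct_A = 150L, ct_B = 150L,
                                         ct_C = 150L),
                          module_size = 20L)
    profile <- compute_transcriptional_specificity(sim$expression)
    cfg <- run_config(min_cells = 100L)
    networks <- reconstruct_networks(sim$reference, profile, cfg)
    dense <- sapply(names(networks), function(ct)
      propagation_network(sim$reference, profile, ct, cfg),
      simplify = FALSE)
    c(sim, list(profile = profile, networks = networks, dense = dense,
                cfg = cfg))
  })
}

# Spearman rank correlation computed from first principles, as an oracle.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
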