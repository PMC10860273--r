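# Network similarity metrics, shared/unique accounting, intersections.

test_that("shared-edge similarity: identity, rank reversal, oracle agreement", {
  net <- random_network(30, seed = 1)
  expect_equal(shared_edge_similarity(net, net), 1)

  e <- network_edges(net)
  rev_e <- e
  rev_e$weight <- max(e$weight) + min(e$weight) - e$weight
  expect_equal(shared_edge_similarity(net, ct_network(rev_e)), -1)

  # five shared edges with listed weights vs a brute-force rank correlation
  ea <- tibble::tibble(from = c("a", "a", "b", "c", "d"),
                       to   = c("b", "c", "c", "d", "e"),
                       weight = c(3.0, 1.5, 4.2, 0.7, 2.2))
  eb <- ea
  eb$weight <- c(2.9, 3.1, 0.4, 1.8, 2.0)
  expect_equal(shared_edge_similarity(ct_network(ea), ct_network(eb)),
               spearman_oracle(ea$weight, eb$weight))
})

test_that("similarity is undefined (NA), not zero, under insufficient overlap", {
  a <- ct_network(tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                                 weight = c(1, 2)))
  b <- ct_network(tibble::tibble(from = c("a", "x"), to = c("b", "y"),
                                 weight = c(1, 2)))
  expect_true(is.na(shared_edge_similarity(a, b)))   # only 1 shared edge
  d <- ct_network(tibble::tibble(from = "p", to = "q", weight = 1))
  # the single-edge network also triggers the degenerate-null warning
  expect_warning(rho_nd <- topology_similarity(a, d), "fewer than 2 edges")
  expect_true(is.na(rho_nd))                         # no shared nodes
  counts <- shared_unique_counts(a, d)
  expect_true(is.na(counts$unique_to_shared_edge_ratio))
})

test_that("topology similarity is rank-invariant to the logistic transform", {
  a <- random_network(50, seed = 2, cell_type = "a")
  b <- random_network(50, seed = 3, cell_type = "b")
  sa <- topological_specificity(a)
  sb <- topological_specificity(b)
  rho <- topology_similarity(a, b, sa, sb)
  shared <- intersect(network_nodes(a), network_nodes(b))
  raw_rho <- spearman_oracle(sa$topS[match(shared, sa$gene)],
                             sb$topS[match(shared, sb$gene)])
  expect_equal(rho, raw_rho, tolerance = 1e-12)
  expect_equal(topology_similarity(a, a, sa, sa), 1)
})

test_that("shared/unique accounting follows set arithmetic", {
  mk <- function(pairs) {
    ct_network(tibble::tibble(from = pairs[, 1], to = pairs[, 2], weight = 1))
  }
  a <- mk(cbind(letters[1:5], letters[2:6]))
  expect_equal(shared_unique_counts(a, a)$unique_to_shared_edge_ratio, 0)
  expect_equal(shared_unique_counts(a, a)$unique_to_shared_node_ratio, 0)

  # |A| = |B| = 5 edges, 3 shared -> (2 + 2) / 3
  b <- mk(cbind(c("a", "b", "c", "x", "y"), c("b", "c", "d", "y", "z")))
  expect_equal(shared_unique_counts(a, b)$n_shared_edges, 3)
  expect_equal(shared_unique_counts(a, b)$unique_to_shared_edge_ratio, 4 / 3)
})

test_that("network intersection keeps only common edges with mean or min weights", {
  net <- random_network(25, seed = 4)
  self_int <- network_intersection(list(net, net))
  expect_equal(network_edges(self_int)[, c("from", "to")],
               network_edges(net)[, c("from", "to")])
  expect_equal(network_edges(self_int)$weight, network_edges(net)$weight)

  tri <- tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"),
                        weight = c(1, 2, 3))
  n1 <- ct_network(dplyr::bind_rows(tri, tibble::tibble(from = "x", to = "y",
                                                        weight = 9)))
  n2 <- ct_network(dplyr::bind_rows(tri, tibble::tibble(from = "p", to = "q",
                                                        weight = 8)))
  tri2 <- tri
  tri2$weight <- c(3, 4, 5)
  n3 <- ct_network(tri2)
  res <- network_intersection(list(n1, n2, n3))
  expect_setequal(paste(network_edges(res)$from, network_edges(res)$to),
                  paste(tri$from, tri$to))
  expect_equal(sort(network_edges(res)$weight),
               sort((2 * tri$weight + tri2$weight) / 3))
  res_min <- network_intersection(list(n1, n3), weight_rule = "min")
  expect_equal(sort(network_edges(res_min)$weight), sort(tri$weight))

  # intersection is bounded by the smallest input and may be empty
  expect_lte(nrow(network_edges(res)),
             min(nrow(network_edges(n1)), nrow(network_edges(n2))))
  disjoint <- ct_network(tibble::tibble(from = "u", to = "v", weight = 1))
  expect_warning(empty <- network_intersection(list(n1, disjoint)), "empty")
  expect_equal(nrow(network_edges(empty)), 0)
})

test_that("similarity panels are symmetric in construction and labeled", {
  nets <- list(a = random_network(40, seed = 5, cell_type = "a"),
               b = random_network(40, seed = 6, cell_type = "b"),
               c = random_network(40, seed = 7, cell_type = "c"))
  panel <- similarity_panel(nets)
  expect_equal(nrow(panel), 3)
  expect_true(all(panel$topology_similarity >= -1 &
                    panel$topology_similarity <= 1, na.rm = TRUE))
  # direction does not matter
  ab <- compare_networks(nets$a, nets$b)
  ba <- compare_networks(nets$b, nets$a)
  expect_equal(ab$edge_similarity, ba$edge_similarity)
  expect_equal(ab$topology_similarity, ba$topology_similarity)
})
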