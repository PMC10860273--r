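# Local networks, hypergeometric enrichment, connectivity statistics and
# their permutation null, hub/neighbor rankings.

test_that("local networks are induced subgraphs within the query radius", {
  path <- ct_network(tibble::tibble(from = c("A", "B", "C"),
                                    to = c("B", "C", "D"),
                                    weight = c(1, 2, 3)))
  ln <- local_network(path, "A", radius = 2)
  expect_setequal(network_nodes(ln), c("A", "B", "C"))
  expect_equal(nrow(network_edges(ln)), 2)

  # star with a chord: radius-1 around the centre keeps leaf-leaf edges too
  star <- ct_network(tibble::tibble(from = c("S", "S", "S", "L1"),
                                    to = c("L1", "L2", "L3", "L2"),
                                    weight = c(1, 1, 1, 5)))
  ln2 <- local_network(star, "S", radius = 1)
  expect_equal(nrow(network_edges(ln2)), 4)

  iso <- ct_network(tibble::tibble(from = "A", to = "B", weight = 1),
                    nodes = c("A", "B", "Z"))
  ln3 <- local_network(iso, "Z")
  expect_equal(network_nodes(ln3), "Z")
  expect_equal(nrow(network_edges(ln3)), 0)

  expect_error(local_network(path, "Q"), "not in network")
})

test_that("hypergeometric p equals exhaustive enumeration", {
  # N = 10, K = 4, n = 5: P(X >= 4) by enumerating all C(10, 5) draws
  universe <- letters[1:10]
  set_genes <- letters[1:4]
  draws <- combn(10, 5)
  overlap <- apply(draws, 2, function(d) sum(d <= 4))
  p_enum <- mean(overlap >= 4)
  sets <- tibble::tibble(set = "s", description = "d",
                         genes = list(set_genes))
  res <- hypergeometric_enrichment(sets, letters[1:5], universe)
  # the query a..e overlaps the set a..d in k = 4 genes
  expect_equal(res$overlap, 4)
  expect_equal(res$p, p_enum, tolerance = 1e-12)

  # sweep all small configurations against enumeration
  for (N in c(6, 9, 12)) {
    uni <- paste0("g", seq_len(N))
    for (K in c(2, floor(N / 2))) {
      for (n in c(2, floor(N / 2), N - 1)) {
        q <- uni[seq_len(n)]
        s <- tibble::tibble(set = "s", description = "",
                            genes = list(uni[seq_len(K)]))
        k_obs <- length(intersect(q, s$genes[[1]]))
        dr <- combn(N, n)
        p_ref <- mean(apply(dr, 2, function(d) sum(d <= K)) >= k_obs)
        expect_equal(hypergeometric_enrichment(s, q, uni)$p, p_ref,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("query equal to the universe gives p = 1 for every set", {
  uni <- paste0("g", 1:8)
  sets <- tibble::tibble(set = c("s1", "s2"), description = "",
                         genes = list(uni[1:3], uni[2:6]))
  res <- hypergeometric_enrichment(sets, uni, uni)
  expect_equal(res$p, c(1, 1))
  expect_equal(res$overlap, res$set_size_in_universe)
})

test_that("BH adjustment matches the hand-computed step-up", {
  uni <- paste0("g", 1:40)
  # craft four sets to produce four distinct p-values, then check q = BH(p)
  sets <- tibble::tibble(set = paste0("s", 1:4), description = "",
                         genes = list(uni[1:10], uni[1:20], uni[11:25],
                                      uni[26:30]))
  res <- hypergeometric_enrichment(sets, uni[1:10], uni)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # the worked step-up case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("within-group connectivity sums internal edges and ignores absent genes", {
  tri <- ct_network(tibble::tibble(from = c("a", "a", "b"),
                                   to = c("b", "c", "c"),
                                   weight = c(1, 1, 1)))
  expect_equal(within_group_connectivity(tri, c("a", "b", "c")), 1)
  expect_equal(within_group_connectivity(tri, c("a", "b", "c", "nope")), 1)
  expect_equal(within_group_connectivity(tri, c("a", "b", "c"),
                                         normalization = "sum"), 3)
  expect_equal(within_group_connectivity(tri, c("a", "b", "c"),
                                         normalization = "per_pair"), 1)
  # no internal edges
  sq <- ct_network(tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                                  weight = c(1, 1)))
  expect_equal(within_group_connectivity(sq, c("a", "c")), 0)
  expect_true(is.na(within_group_connectivity(sq, c("a", "zz"))))
})

test_that("connectivity permutation test: degenerate null, bounds, determinism", {
  net <- random_network(30, seed = 1)
  res <- connectivity_permutation_test(net, network_nodes(net),
                                       n_permutations = 200, seed = 5)
  expect_equal(res$empirical_p, 1)   # every null set is the full node set

  res1 <- connectivity_permutation_test(net, network_nodes(net)[1:6],
                                        n_permutations = 300, seed = 9)
  res2 <- connectivity_permutation_test(net, network_nodes(net)[1:6],
                                        n_permutations = 300, seed = 9)
  expect_identical(res1, res2)
  expect_gt(res1$empirical_p, 0)
  expect_lte(res1$empirical_p, 1)
  expect_error(connectivity_permutation_test(net, network_nodes(net)[1:4],
                                             n_permutations = 50),
               ">= 100")
})

test_that("scaled connectivity is a centred, unit-variance profile and identical networks score 0", {
  nets <- list(a = random_network(40, seed = 2),
               b = random_network(40, seed = 3),
               c = random_network(40, seed = 4))
  genes <- network_nodes(nets$a)[1:8]
  res <- scaled_connectivity(nets, genes, n_permutations = 200, seed = 3)
  expect_equal(mean(res$scaled), 0, tolerance = 1e-12)
  expect_equal(sd(res$scaled), 1, tolerance = 1e-12)

  # identical networks carry no deconvolution signal: exactly the 0 vector
  net <- nets$a
  same <- scaled_connectivity(list(a = net, b = net, c = net), genes,
                              n_permutations = 200, seed = 3)
  expect_equal(same$scaled, rep(0, 3))
})

test_that("hub and neighbor rankings order by strength with symbol tie-breaks", {
  star <- ct_network(tibble::tibble(from = rep("hub", 5),
                                    to = paste0("leaf", 1:5),
                                    weight = rep(1, 5)))
  hr <- hub_rankings(star, c("hub", "leaf1"))
  expect_equal(hr$members$gene[1], "hub")
  expect_equal(hr$members$strength[1], 5)

  # neighbor connected to 3 members (1+2+3) outranks one with a single 5
  net <- ct_network(tibble::tibble(
    from = c("m1", "m2", "m3", "m1"),
    to = c("n1", "n1", "n1", "n2"),
    weight = c(1, 2, 3, 5)
  ))
  hr2 <- hub_rankings(net, c("m1", "m2", "m3"))
  expect_equal(hr2$neighbors$gene, c("n1", "n2"))
  expect_equal(hr2$neighbors$strength_to_set, c(6, 5))

  # a set with no external neighbors yields an empty neighbor ranking
  closed <- ct_network(tibble::tibble(from = "a", to = "b", weight = 1))
  expect_equal(nrow(hub_rankings(closed, c("a", "b"))$neighbors), 0)

  # ties broken by symbol
  tie <- ct_network(tibble::tibble(from = c("a", "b"), to = c("x", "y"),
                                   weight = c(1, 1)))
  expect_equal(hub_rankings(tie, c("a", "b"))$members$gene, c("a", "b"))
})

test_that("planted modules deconvolve to their own cell type", {
  st <- small_study()
  mod <- st$truth$planted_modules[["ct_B"]]
  own <- connectivity_permutation_test(st$dense$ct_B, mod,
                                       n_permutations = 500, seed = 11)
  other <- connectivity_permutation_test(st$dense$ct_A, mod,
                                         n_permutations = 500, seed = 11)
  expect_lte(own$empirical_p, 0.01)
  expect_true(is.na(other$empirical_p) || other$empirical_p > 0.05)

  sc <- scaled_connectivity(st$dense, mod, n_permutations = 300, seed = 7)
  expect_equal(sc$cell_type[which.max(sc$scaled)], "ct_B")
})
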