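# Random walk with restart, degree-preserving rewiring, AUPRC, and
# performance against null networks.

test_that("gamma = 1 returns the restart vector exactly", {
  net <- toy_network()
  res <- rwr(net, c("A", "B"), gamma = 1)
  expect_equal(res$p_star, res$p0)
})

test_that("two-node network with seed A converges to (2/3, 1/3)", {
  net <- ct_network(tibble::tibble(from = "A", to = "B", weight = 1))
  res <- rwr(net, "A", gamma = 0.5, tol = 1e-12)
  expect_equal(unname(res$p_star), c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("iterated RWR matches the direct linear solve on random graphs", {
  for (seed in 1:5) {
    net <- random_network(50, seed = seed)
    nodes <- network_nodes(net)
    seeds <- nodes[1:3]
    res <- rwr(net, seeds, gamma = 0.5, tol = 1e-12)
    W <- as.matrix(ctnet:::column_normalized_adjacency(net))
    p0 <- setNames(numeric(length(nodes)), nodes)
    p0[seeds] <- 1 / 3
    direct <- solve(diag(length(nodes)) - 0.5 * W, 0.5 * p0)
    expect_lt(sum(abs(res$p_star - direct)), 1e-8)
    expect_equal(sum(res$p_star), 1, tolerance = 1e-8)
  }
})

test_that("p_star is invariant to uniform edge-weight scaling", {
  net <- random_network(40, seed = 3)
  e <- network_edges(net)
  e$weight <- e$weight * 123
  scaled <- ct_network(e)
  expect_equal(rwr(net, network_nodes(net)[1])$p_star,
               rwr(scaled, network_nodes(net)[1])$p_star, tolerance = 1e-9)
})

test_that("prioritize excludes seeds and strands seedless components at zero", {
  net <- toy_network()
  all_genes <- network_nodes(net)
  expect_equal(nrow(prioritize(net, all_genes)), 0)

  two_comp <- ct_network(tibble::tibble(
    from = c("a", "b", "x"), to = c("b", "c", "y"),
    weight = c(1, 1, 1)
  ))
  res <- prioritize(two_comp, "a")
  expect_equal(res$gene[1:2], c("b", "c"))
  expect_equal(res$p_star[res$gene %in% c("x", "y")], c(0, 0))
  expect_error(rwr(two_comp, "zzz"), "no seed")
})

test_that("rewiring preserves degrees and the weight multiset", {
  net <- random_network(60, seed = 12)
  rew <- degree_preserving_rewire(net, seed = 1)
  deg <- function(n) {
    e <- network_edges(n)
    tab <- table(factor(c(e$from, e$to), levels = network_nodes(n)))
    as.integer(tab)
  }
  expect_identical(deg(rew), deg(net))
  expect_equal(sort(network_edges(rew)$weight),
               sort(network_edges(net)$weight))
  expect_identical(network_nodes(rew), network_nodes(net))
  # 4-cycle: all degrees stay 2, graph stays simple
  cyc <- ct_network(tibble::tibble(from = c("a", "b", "c", "a"),
                                   to = c("b", "c", "d", "d"),
                                   weight = 1:4))
  r2 <- degree_preserving_rewire(cyc, seed = 2)
  expect_true(all(deg(r2) == 2))
  expect_equal(anyDuplicated(ctnet:::edge_key(network_edges(r2))), 0)
  # deterministic given the seed
  expect_identical(network_edges(degree_preserving_rewire(net, seed = 7)),
                   network_edges(degree_preserving_rewire(net, seed = 7)))
})

test_that("AUPRC is 1 for perfect rankings and ~prevalence for random scores", {
  scores <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  expect_equal(auprc(scores, c("a", "b")), 1)
  expect_equal(auprc(scores, "e"), 1 / 5)
  # tiny enumerable case: positives ranked 2nd and 4th
  expect_equal(auprc(scores, c("b", "d")), mean(c(1 / 2, 2 / 4)))

  set.seed(31)
  prev <- replicate(200, {
    s <- setNames(runif(40), paste0("i", 1:40))
    auprc(s, paste0("i", 1:8))
  })
  expect_lt(abs(mean(prev) - 0.2), 0.1)
})

test_that("recovery AUPRC is deterministic and separates structure from rewired nulls", {
  net <- random_network(80, seed = 21)
  genes <- network_nodes(net)[1:10]
  a1 <- geneset_recovery_auprc(net, genes, seed = 5)
  a2 <- geneset_recovery_auprc(net, genes, seed = 5)
  expect_identical(a1, a2)

  # positives isolated with the seeds in a private component get AUPRC 1
  private <- ct_network(tibble::tibble(
    from = c("s1", "s1", "p1", "o1"),
    to = c("p1", "p2", "p2", "o2"),
    weight = 1
  ))
  val <- ctnet:::recovery_auprc_with_splits(
    private, list(list(seeds = "s1", held_out = c("p1", "p2"))),
    gamma = 0.5, tol = 1e-10
  )
  expect_equal(val, 1)
})

test_that("performance and gain summarize the null ensemble robustly", {
  st <- small_study()
  mod <- st$truth$planted_modules[["ct_A"]]
  perf <- performance_and_gain(st$dense$ct_A, mod, n_null = 10,
                               repeats = 4, seed = 2)
  g <- glance(perf)
  expect_equal(g$null_median, median(perf$null_auprcs))
  expect_equal(g$performance,
               (perf$auprc - median(perf$null_auprcs)) /
                 mad(perf$null_auprcs))
  expect_equal(g$gain,
               (perf$auprc - median(perf$null_auprcs)) /
                 median(perf$null_auprcs))
  expect_gt(perf$gain, 0)
  # gain is invariant to common rescaling of all AUPRCs
  fake <- perf
  fake$null_auprcs <- perf$null_auprcs * 3
  fake$auprc <- perf$auprc * 3
  expect_equal((fake$auprc - median(fake$null_auprcs)) /
                 median(fake$null_auprcs), perf$gain)
  expect_error(performance_and_gain(st$dense$ct_A, mod, n_null = 5),
               ">= 10")
})
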