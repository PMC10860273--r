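# Synthetic data with known ground truth: reference networks, labeled
# negative-binomial UMI counts with planted cell-type-specific modules that
# coincide with connected subgraphs of the reference, and matched gene sets.

#' Generate a synthetic reference interactome
#'
#' Produces a connected simple graph over genes labeled `g0001...`, either by
#' preferential attachment (scale-free-like degree distribution, as in curated
#' interactomes) or by a Poisson configuration model. Only the largest
#' connected component is retained (logged when nodes are dropped).
#'
#' @param n_genes number of genes (>= 10) before pruning to the largest
#'   component.
#' @param mean_degree target mean degree (>= 1).
#' @param model `"preferential_attachment"` (attachment `m = mean_degree / 2`
#'   rounded, so `|E| = m n - m (m + 1) / 2`) or `"configuration"`.
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return an [interactome].
#' @export
generate_reference_network <- function(n_genes, mean_degree = 4,
                                       model = c("preferential_attachment",
                                                 "configuration"),
                                       seed = 1L) {
  model <- match.arg(model)
  if (n_genes < 10) abort("n_genes must be >= 10")
  if (mean_degree < 1) abort("mean_degree must be >= 1")
  g <- local_seed(seed, {
    if (model == "preferential_attachment") {
      m <- max(1L, as.integer(round(mean_degree / 2)))
      igraph::sample_pa(n_genes, m = m, directed = FALSE)
    } else {
      deg <- pmax(1L, stats::rpois(n_genes, mean_degree))
      if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
      if (!igraph::is_graphical(deg))
        abort("infeasible degree sequence for configuration model")
      igraph::sample_degseq(deg, method = "vl")
    }
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- padded_ids("g", igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    keep <- which(comp$membership == which.max(comp$csize))
    ct_log("generate_reference_network: retained largest component (",
           length(keep), " of ", igraph::vcount(g), " nodes)")
    g <- igraph::induced_subgraph(g, keep)
  }
  el <- igraph::as_data_frame(g, what = "edges")
  interactome(tibble(from = el$from, to = el$to),
              name = paste0("synthetic_", model),
              nodes = igraph::V(g)$name)
}

# Grow one connected module of `size` nodes by seeded breadth-first expansion
# from a random start, restricted to `available` nodes. Returns NULL if the
# start cannot reach `size` nodes.
grow_module <- function(adj, available, size, start) {
  members <- start
  frontier <- start
  avail <- available
  avail[start] <- FALSE
  while (length(members) < size && length(frontier) > 0) {
    nbrs <- unique(unlist(adj[frontier], use.names = FALSE))
    nbrs <- nbrs[avail[nbrs]]
    if (length(nbrs) == 0) break
    take <- head(nbrs, size - length(members))
    members <- c(members, take)
    avail[take] <- FALSE
    frontier <- take
  }
  if (length(members) < size) NULL else members
}

# Choose disjoint connected modules, one per label, by bounded retries.
sample_modules <- function(reference, labels, module_size, max_tries = 200L) {
  g <- as_igraph(reference)
  nodes <- igraph::V(g)$name
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, as.integer)
  for (try in seq_len(max_tries)) {
    available <- rep(TRUE, length(nodes))
    modules <- list()
    ok <- TRUE
    for (lab in labels) {
      starts <- sample(which(available))
      found <- NULL
      for (s in head(starts, 25L)) {
        found <- grow_module(adj, available, module_size, s)
        if (!is.null(found)) break
      }
      if (is.null(found)) { ok <- FALSE; break }
      available[found] <- FALSE
      modules[[lab]] <- sort(nodes[found])
    }
    if (ok) return(modules)
  }
  abort("could not place disjoint connected modules; reduce module_size")
}

# Induced reference edges among a module's genes.
module_edges <- function(reference, genes) {
  e <- reference$edges
  e[e$from %in% genes & e$to %in% genes, c("from", "to")]
}

#' Generate labeled single-cell counts with planted cell-type modules
#'
#' Counts follow a negative-binomial model with variance
#' `mu + dispersion * mu^2`. For cell `c` and gene `g`,
#' `mu = depth_c * exp(b_g + log(2) * lfc[ct(c), g])`, where the baseline
#' `b_g ~ Normal(baseline_log_mean_mu, baseline_log_mean_sd)` and `depth_c` is
#' lognormal around `depth_mean` (sdlog `depth_sdlog`), so specificity
#' statistics are exercised against uneven library sizes. The log2 fold
#' change `lfc` is `module_log2fc` for genes of the cell type's planted
#' module — a connected subgraph of the reference grown breadth-first from a
#' random node, disjoint across cell types — and zero elsewhere, unless a
#' broad cell-type program is enabled (`program_frac > 0`), in which case a
#' fraction of the non-module genes per cell type additionally receives
#' `lfc ~ Normal(0, program_log2fc_sd)`.
#'
#' @param reference an [interactome] providing the gene universe and the
#'   subgraphs modules are planted on.
#' @param cell_types named integer vector: cells per cell-type label.
#' @param module_size genes per planted module.
#' @param module_log2fc planted log2 fold change (delta > 0; 0 disables
#'   planting for calibration runs).
#' @param nb_dispersion NB dispersion phi in `var = mu + phi mu^2`.
#' @param depth_mean mean library-size factor.
#' @param seed RNG seed; output is bit-identical given the seed.
#' @param baseline_log_mean_mu,baseline_log_mean_sd baseline log-mean
#'   distribution (natural log scale).
#' @param depth_sdlog lognormal sdlog of the per-cell depth factor.
#' @param program_frac fraction of non-module genes given a cell-type
#'   program effect (default 0: the pure planted-module model).
#' @param program_log2fc_sd sd of program log2 fold changes.
#' @param n_samples samples to assign cells to (round-robin).
#' @param modules,program optional preset module membership / program tables
#'   (as found in a `synthetic_truth`), used to share the cell-type signal
#'   across panel contexts.
#' @return list with `expression` (an [expression_dataset]) and `truth`
#'   (a `synthetic_truth`: planted modules, their reference subgraph edges,
#'   baseline log-means, program tables, and the generator parameters).
#' @export
generate_expression <- function(reference, cell_types, module_size = 20L,
                                module_log2fc = 2, nb_dispersion = 0.2,
                                depth_mean = 10, seed = 1L,
                                baseline_log_mean_mu = -2,
                                baseline_log_mean_sd = 1,
                                depth_sdlog = 0.3,
                                program_frac = 0, program_log2fc_sd = 0,
                                n_samples = 2L,
                                modules = NULL, program = NULL) {
  stopifnot(inherits(reference, "interactome"))
  if (is.null(names(cell_types)) || any(!nzchar(names(cell_types))))
    abort("cell_types must be a named vector: cells per cell-type label")
  if (nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (module_log2fc < 0) abort("module_log2fc must be >= 0")
  labels <- names(cell_types)
  genes <- reference$nodes
  G <- length(genes)
  if (module_size * length(labels) > G)
    abort("module_size x number of cell types exceeds the gene universe")

  local_seed(seed, {
    if (is.null(modules)) {
      modules <- if (module_log2fc > 0)
        sample_modules(reference, labels, module_size)
      else
        setNames(replicate(length(labels),
                           sort(sample(genes, module_size)),
                           simplify = FALSE), labels)
    }
    module_genes_all <- unlist(modules, use.names = FALSE)
    if (is.null(program)) {
      # Each cell type also up-regulates a broad expression program. Program
      # genes are grown as a connected region of the reference (co-functional
      # genes cluster on the interactome), with half-normal log2 fold
      # changes; regions of different cell types may overlap.
      program <- setNames(vector("list", length(labels)), labels)
      g_ref <- as_igraph(reference)
      adj <- lapply(igraph::adjacent_vertices(g_ref, igraph::V(g_ref)),
                    as.integer)
      pool_ok <- !(genes %in% module_genes_all)
      n_prog <- floor(program_frac * sum(pool_ok))
      for (lab in labels) {
        if (n_prog > 0 && program_log2fc_sd > 0) {
          pg <- NULL
          for (s in sample(which(pool_ok), min(25L, sum(pool_ok)))) {
            pg <- grow_module(adj, pool_ok, n_prog, s)
            if (!is.null(pg)) break
          }
          if (is.null(pg))
            abort("could not grow a connected program region")
          pg <- sort(genes[pg])
          program[[lab]] <- tibble(gene = pg,
                                   log2fc = abs(rnorm(n_prog, 0,
                                                      program_log2fc_sd)))
        } else {
          program[[lab]] <- tibble(gene = character(), log2fc = numeric())
        }
      }
    }
    baseline <- setNames(rnorm(G, baseline_log_mean_mu, baseline_log_mean_sd),
                         genes)

    n_total <- sum(cell_types)
    depth <- rlnorm(n_total, meanlog = log(depth_mean) - depth_sdlog^2 / 2,
                    sdlog = depth_sdlog)
    blocks <- vector("list", length(labels))
    offset <- 0L
    for (k in seq_along(labels)) {
      lab <- labels[k]
      n_c <- cell_types[[k]]
      lfc <- setNames(numeric(G), genes)
      lfc[modules[[lab]]] <- module_log2fc
      if (nrow(program[[lab]]) > 0)
        lfc[program[[lab]]$gene] <- lfc[program[[lab]]$gene] +
          program[[lab]]$log2fc
      gene_mu <- exp(baseline + log(2) * lfc)
      mu <- outer(depth[offset + seq_len(n_c)], gene_mu)
      blocks[[k]] <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / nb_dispersion),
                            nrow = n_c, ncol = G)
      offset <- offset + n_c
    }
    counts <- do.call(rbind, blocks)
    cell_ids <- padded_ids("c", n_total)
    dimnames(counts) <- list(cell_ids, genes)
    ct_labels <- rep(labels, times = as.integer(cell_types))
    sample_ids <- paste0("smp", (seq_len(n_total) - 1L) %% n_samples + 1L)
    expr <- expression_dataset(counts, cell_type = ct_labels,
                               sample = sample_ids)
    truth <- structure(
      list(
        planted_modules = modules,
        module_log2fc = module_log2fc,
        baseline_log_mean = baseline,
        nb_dispersion = nb_dispersion,
        module_subgraph_edges = lapply(modules, module_edges,
                                       reference = reference),
        program = program,
        depth_mean = depth_mean,
        seed = as.integer(seed)
      ),
      class = "synthetic_truth"
    )
    list(expression = expr, truth = truth)
  })
}

#' Gene sets matched to a synthetic truth
#'
#' One gene set per planted module (named `module_<cell type>`) plus
#' `n_random` size-matched sets drawn uniformly from the reference nodes,
#' for calibration of the connectivity and enrichment machinery.
#'
#' @param truth a `synthetic_truth`.
#' @param reference the [interactome] the truth was planted on.
#' @param n_random number of random null sets (>= 0).
#' @param seed RNG seed.
#' @return gene-set tibble (`set`, `description`, `genes`), as [read_gmt()].
#' @export
generate_gene_sets <- function(truth, reference, n_random = 0L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mods <- truth$planted_modules
  module_size <- length(mods[[1]])
  sets <- tibble(
    set = paste0("module_", names(mods)),
    description = paste0("planted module, log2FC=", truth$module_log2fc),
    genes = unname(mods)
  )
  if (n_random > 0) {
    rnd <- local_seed(seed, {
      lapply(seq_len(n_random), function(i)
        sort(sample(reference$nodes, module_size)))
    })
    sets <- bind_rows(sets, tibble(
      set = sprintf("random_%03d", seq_len(n_random)),
      description = "size-matched uniform null set",
      genes = rnd
    ))
  }
  sets
}

#' Simulate a complete study with known ground truth
#'
#' Bundles the generator stages under the package's standing study
#' conditions: a preferential-attachment reference over `n_genes` genes,
#' three (by default) cell types of 500 cells each, one planted connected
#' module of `module_size` co-upregulated genes per cell type
#' (`module_log2fc` = 2), and a broad per-cell-type program of mildly
#' differentially expressed background genes (30% of non-module genes,
#' log2FC sd 0.5) emulating the genome-wide expression differences real cell
#' types show — without it, reconstructed networks would contain little
#' beyond the planted module itself.
#'
#' @param seed RNG seed driving every stage.
#' @param n_genes,mean_degree reference network size and density.
#' @param cell_types named vector of cells per cell type.
#' @param module_size,module_log2fc,nb_dispersion,depth_mean see
#'   [generate_expression()].
#' @param program_frac,program_log2fc_sd broad cell-type program parameters.
#' @param n_random_sets random gene sets to generate alongside the modules.
#' @return list with `reference`, `expression`, `truth`, `gene_sets`.
#' @export
simulate_study <- function(seed = 1L, n_genes = 5000L, mean_degree = 4,
                           cell_types = c(ct_A = 500L, ct_B = 500L,
                                          ct_C = 500L),
                           module_size = 20L, module_log2fc = 2,
                           nb_dispersion = 0.2, depth_mean = 10,
                           program_frac = 0.3, program_log2fc_sd = 0.5,
                           n_random_sets = 5L) {
  reference <- generate_reference_network(n_genes, mean_degree,
                                          "preferential_attachment",
                                          seed = seed)
  sim <- generate_expression(reference, cell_types,
                             module_size = module_size,
                             module_log2fc = module_log2fc,
                             nb_dispersion = nb_dispersion,
                             depth_mean = depth_mean,
                             program_frac = program_frac,
                             program_log2fc_sd = program_log2fc_sd,
                             seed = seed + 1L)
  gene_sets <- generate_gene_sets(sim$truth, reference,
                                  n_random = n_random_sets, seed = seed + 2L)
  list(reference = reference, expression = sim$expression,
       truth = sim$truth, gene_sets = gene_sets)
}

#' Simulate a panel of contexts sharing cell-type signal
#'
#' Emulates the same cell types profiled across several "tumor types": the
#' planted modules and cell-type programs are held fixed across contexts
#' while baselines, depths and counts are resampled, so networks for the
#' same cell type should resemble each other across contexts more than
#' networks for different cell types do.
#'
#' @inheritParams simulate_study
#' @param n_contexts number of contexts (datasets) to generate.
#' @return list with `reference`, `truth` (shared), and `expression`: a named
#'   list of [expression_dataset]s, one per context.
#' @export
simulate_panel <- function(n_contexts = 2L, seed = 1L, n_genes = 2000L,
                           mean_degree = 4,
                           cell_types = c(ct_A = 500L, ct_B = 500L,
                                          ct_C = 500L),
                           module_size = 20L, module_log2fc = 2,
                           nb_dispersion = 0.2, depth_mean = 10,
                           program_frac = 0.3, program_log2fc_sd = 0.5) {
  reference <- generate_reference_network(n_genes, mean_degree,
                                          "preferential_attachment",
                                          seed = seed)
  first <- generate_expression(reference, cell_types,
                               module_size = module_size,
                               module_log2fc = module_log2fc,
                               nb_dispersion = nb_dispersion,
                               depth_mean = depth_mean,
                               program_frac = program_frac,
                               program_log2fc_sd = program_log2fc_sd,
                               seed = seed + 1L)
  contexts <- vector("list", n_contexts)
  contexts[[1]] <- first$expression
  if (n_contexts > 1) {
    for (i in 2:n_contexts) {
      contexts[[i]] <- generate_expression(
        reference, cell_types,
        module_size = module_size, module_log2fc = module_log2fc,
        nb_dispersion = nb_dispersion, depth_mean = depth_mean,
        program_frac = program_frac, program_log2fc_sd = program_log2fc_sd,
        seed = seed + i,
        modules = first$truth$planted_modules,
        program = first$truth$program
      )$expression
    }
  }
  names(contexts) <- paste0("context_", seq_len(n_contexts))
  list(reference = reference, truth = first$truth, expression = contexts)
}
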