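# Seeded synthetic-data generators: preferential-attachment and
# Erdos-Renyi interactomes, chemical-target tables with a planted
# densely-wired target module (to emulate the non-random wiring of real
# SM target sets), and compound universes with exact overlap structure
# for Fisher tests. All generators take explicit seeds; none touches
# global random state beyond a local set.seed().

#' Synthetic study specification
#'
#' Bundles the knobs of the synthetic generators with defaults matching
#' the package's study conditions: a 3000-node preferential-attachment
#' interactome (2 edges per new node), a 100-node planted module, and 5
#' chemicals drawing 30 targets each entirely from the module
#' (purity 1).
#'
#' @param n_nodes Interactome size.
#' @param attachment_edges Edges added per new node (preferential
#'   attachment).
#' @param er_edge_prob Edge probability for the random-graph control.
#' @param planted_module_size Size of the planted dense module.
#' @param purity Probability that a planted target is drawn from the
#'   module (1 = pure signal, 0 = uniform outside the module).
#' @param n_chemicals Number of synthetic chemicals.
#' @param targets_per_chemical Distinct targets drawn per chemical.
#' @param seed Master seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 3000, attachment_edges = 2,
                           er_edge_prob = 0.005,
                           planted_module_size = 100, purity = 1,
                           n_chemicals = 5, targets_per_chemical = 30,
                           seed = 1) {
  stopifnot(purity >= 0, purity <= 1,
            planted_module_size <= n_nodes,
            n_nodes > attachment_edges, attachment_edges >= 1)
  structure(list(n_nodes = n_nodes, attachment_edges = attachment_edges,
                 er_edge_prob = er_edge_prob,
                 planted_module_size = planted_module_size,
                 purity = purity, n_chemicals = n_chemicals,
                 targets_per_chemical = targets_per_chemical,
                 seed = seed),
            class = "synthetic_spec")
}

.name_nodes <- function(g, prefix = "G") {
  igraph::V(g)$name <- sprintf("%s%05d", prefix, seq_len(igraph::vcount(g)))
  g
}

#' Generate a scale-free interactome by preferential attachment
#'
#' Growth model: each new node attaches to `m` existing nodes with
#' probability proportional to their degree, yielding a connected simple
#' graph with a heavy-tailed degree distribution. Deterministic given
#' (`n`, `m`, `seed`).
#'
#' @param n Number of nodes (> m).
#' @param m Edges per new node (>= 1).
#' @param seed Seed.
#' @return An `interactome`.
#' @export
gen_scale_free <- function(n, m, seed) {
  if (n <= m) stop("n must exceed m", call. = FALSE)
  stopifnot(m >= 1)
  set.seed(seed)
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  as_interactome(.name_nodes(g))
}

#' Generate an Erdos-Renyi interactome
#'
#' Each unordered node pair is an edge independently with probability
#' `p`; the density-matched control for topology comparisons.
#'
#' @param n Number of nodes.
#' @param p Edge probability in \[0, 1\].
#' @param seed Seed.
#' @return An `interactome`.
#' @export
gen_er <- function(n, p, seed) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  as_interactome(.name_nodes(g))
}

#' Generate a chemical-target table with a planted dense module
#'
#' The planted module is the `planted_module_size`-node set with the
#' highest total internal degree, taken as the top-degree nodes (ties
#' broken by node name) — in a preferential-attachment graph these hubs
#' form the densely wired core, so targets drawn from the module are far
#' more interconnected than uniform draws, emulating the elevated
#' interconnectivity of real SM target sets. Each chemical draws
#' `targets_per_chemical` distinct proteins: a Binomial(purity) share
#' from the module, the rest uniformly from outside it. Scores are fixed
#' (combined 0.9; experimental/database channels 0.9, textmining and
#' prediction 0).
#'
#' @param g An `interactome`.
#' @param spec A `synthetic_spec`.
#' @return List with `table` (chemical-target data frame) and `module`
#'   (character vector of module node names).
#' @export
gen_planted_target_map <- function(g, spec) {
  stopifnot(inherits(g, "interactome"), inherits(spec, "synthetic_spec"))
  nodes <- igraph::V(g$graph)$name
  n <- length(nodes)
  if (spec$planted_module_size > n) {
    stop("planted module larger than the graph", call. = FALSE)
  }
  deg <- igraph::degree(g$graph)
  ord <- order(-deg, nodes)
  module <- nodes[ord[seq_len(spec$planted_module_size)]]
  rest <- setdiff(nodes, module)
  tpc <- spec$targets_per_chemical
  if (tpc > n || (spec$purity == 1 && tpc > length(module)) ||
      (spec$purity == 0 && tpc > length(rest))) {
    stop("targets_per_chemical exceeds the available target pool",
         call. = FALSE)
  }
  set.seed(derive_seed(spec$seed, "planted-targets"))
  rows <- lapply(seq_len(spec$n_chemicals), function(j) {
    n_mod <- stats::rbinom(1, tpc, spec$purity)
    n_mod <- min(n_mod, length(module))
    n_mod <- max(n_mod, tpc - length(rest))
    targets <- c(sample(module, n_mod),
                 if (tpc - n_mod > 0) sample(rest, tpc - n_mod))
    data.frame(chemical_id = sprintf("CHEM%02d", j), protein = targets,
               experimental = 0.9, database = 0.9, textmining = 0,
               prediction = 0, combined_score = 0.9,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), module = module)
}

#' Generate a universe and two sets with exact overlap structure
#'
#' Symbols are synthetic compound IDs; the returned sets have exactly
#' the requested cardinalities and overlap.
#'
#' @param n_universe,n_a,n_b,n_overlap Requested sizes
#'   (`n_overlap <= min(n_a, n_b)`;
#'   `n_a + n_b - n_overlap <= n_universe`).
#' @param seed Seed.
#' @return List with `universe`, `set_a`, `set_b`.
#' @export
gen_overlap_universes <- function(n_universe, n_a, n_b, n_overlap, seed) {
  if (n_overlap > min(n_a, n_b)) {
    stop("requested overlap exceeds the smaller set", call. = FALSE)
  }
  if (n_a + n_b - n_overlap > n_universe) {
    stop("sets do not fit in the universe", call. = FALSE)
  }
  universe <- sprintf("C%05d", seq_len(n_universe))
  set.seed(seed)
  pool <- sample(universe)
  shared <- pool[seq_len(n_overlap)]
  a_only <- pool[n_overlap + seq_len(n_a - n_overlap)]
  b_only <- pool[n_a + seq_len(n_b - n_overlap)]
  list(universe = universe,
       set_a = sort(c(shared, a_only)),
       set_b = sort(c(shared, b_only)))
}
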