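# Shared helpers: tiny graph builders, file fixtures written on the fly,
# and independent oracles (union-find for component sizes, exhaustive
# hypergeometric enumeration for Fisher p-values). The oracles share no
# code with the implementation paths they check.

# interactome from a flat vector of endpoint pairs: c("A","B", "B","C")
toy_interactome <- function(pairs) {
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(m, directed = FALSE)
  as_interactome(g)
}

path_interactome <- function(n, prefix = "V") {
  syms <- paste0(prefix, seq_len(n))
  toy_interactome(as.vector(rbind(syms[-n], syms[-1])))
}

# edge-record data frame in the simple_tsv layout
edge_records <- function(a, b, type = "physical", org_a = 9606,
                         org_b = 9606) {
  data.frame(symbol_a = a, symbol_b = b,
             system_type = rep_len(type, length(a)),
             organism_a = rep_len(org_a, length(a)),
             organism_b = rep_len(org_b, length(a)),
             stringsAsFactors = FALSE)
}

write_simple_edge_file <- function(records, path = tempfile(fileext = ".tsv")) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# edge-list file for a synthetic interactome, in the simple_tsv dialect
write_graph_as_edge_file <- function(g, path = tempfile(fileext = ".tsv")) {
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  write_simple_edge_file(edge_records(el[, 1], el[, 2]), path)
}

write_chem_target_file <- function(table, path = tempfile(fileext = ".tsv")) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# --- independent oracles ---------------------------------------------------

# Largest-connected-component size of the subgraph induced by `query`
# (character symbols) via union-find with path compression; no BFS, no
# igraph.
uf_lcc_size <- function(edge_a, edge_b, query) {
  nodes <- unique(query)
  k <- length(nodes)
  if (k == 0) return(0L)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(edge_a, nodes)
  ib <- match(edge_b, nodes)
  keep <- !is.na(ia) & !is.na(ib)
  for (e in which(keep)) {
    ra <- find(ia[e])
    rb <- find(ib[e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(k), find, integer(1))
  max(table(roots))
}

# One-sided (greater) hypergeometric tail by direct summation of
# binomial-coefficient terms.
enum_hyper_greater <- function(k, n_a, n_b, n_u) {
  lo <- max(0, n_a + n_b - n_u)
  hi <- min(n_a, n_b)
  probs <- choose(n_a, lo:hi) * choose(n_u - n_a, n_b - (lo:hi)) /
    choose(n_u, n_b)
  sum(probs[(lo:hi) >= k])
}

# Two-sided Fisher p by enumeration: sum of outcome probabilities not
# larger than the observed one (with the conventional relative slack for
# floating-point ties).
enum_hyper_two_sided <- function(k, n_a, n_b, n_u) {
  lo <- max(0, n_a + n_b - n_u)
  hi <- min(n_a, n_b)
  probs <- choose(n_a, lo:hi) * choose(n_u - n_a, n_b - (lo:hi)) /
    choose(n_u, n_b)
  obs <- probs[(lo:hi) == k]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
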