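# The interactome: a simple undirected graph over protein symbols,
# obtained from raw edge records by the cleaning rules used throughout
# the analysis — genetic interactions, off-species interactions,
# self-loops and duplicate edges are removed, and per-rule removal
# counts are kept as provenance.

#' Construct an interactome object from an igraph graph
#'
#' @param graph An undirected, simple, named igraph graph.
#' @param provenance Named integer vector of records removed per
#'   cleaning rule (may be empty for synthetic graphs).
#' @return An object of class `interactome`.
#' @export
as_interactome <- function(graph,
                           provenance = c(genetic = 0L, off_species = 0L,
                                          self_loop = 0L, duplicate = 0L)) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph, mode = "collapse")
  if (!igraph::is_simple(graph)) graph <- igraph::simplify(graph)
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- sprintf("G%0*d", nchar(igraph::vcount(graph)),
                                     seq_len(igraph::vcount(graph)))
  }
  structure(list(graph = graph, provenance = provenance),
            class = "interactome")
}

#' Clean raw edge records into an interactome
#'
#' Applies, in order: removal of genetic interactions (only `"physical"`
#' edges are kept), removal of interactions where either organism differs
#' from `taxon`, removal of self-loops, and collapsing of duplicate edges
#' (edges are unordered pairs, so A-B and B-A are the same edge). Nodes
#' are the endpoints of surviving edges; proteins seen only in removed
#' rows are dropped. The count removed by each rule is recorded in
#' `provenance`, and the counts sum to (input rows - surviving edges).
#'
#' @param records Edge-record data frame from [read_edge_list()].
#' @param taxon Positive integer NCBI taxonomy ID to keep (e.g. 9606).
#' @return An object of class `interactome`.
#' @export
clean_interactome <- function(records, taxon) {
  stopifnot(is.numeric(taxon), length(taxon) == 1, taxon > 0)
  require_columns(records,
                  c("symbol_a", "symbol_b", "system_type",
                    "organism_a", "organism_b"), "edge records")
  n0 <- nrow(records)
  if (n0 == 0) {
    warning("no input edge records: empty interactome", call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::V(g)$name <- character(0)
    return(as_interactome(g))
  }
  keep <- records$system_type == "physical"
  n_genetic <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$organism_a == taxon & records$organism_b == taxon
  n_off <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$symbol_a != records$symbol_b
  n_self <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  key <- ifelse(records$symbol_a <= records$symbol_b,
                paste(records$symbol_a, records$symbol_b, sep = "\r"),
                paste(records$symbol_b, records$symbol_a, sep = "\r"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  prov <- c(genetic = n_genetic, off_species = n_off,
            self_loop = n_self, duplicate = n_dup)
  if (nrow(records) == 0) {
    warning("all edge records removed by cleaning: empty interactome",
            call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::V(g)$name <- character(0)
    return(as_interactome(g, prov))
  }
  g <- igraph::graph_from_data_frame(
    records[, c("symbol_a", "symbol_b")], directed = FALSE)
  as_interactome(g, prov)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (sum(x$provenance) > 0) {
    cat("records removed:",
        paste(sprintf("%s %d", names(x$provenance), x$provenance),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Node names of an interactome
#' @param g An `interactome`.
#' @return Character vector of protein symbols.
#' @export
interactome_nodes <- function(g) {
  stopifnot(inherits(g, "interactome"))
  igraph::V(g$graph)$name
}

#' Degree histogram of an interactome
#'
#' Counts, for every observed degree k, the number of nodes with that
#' degree. Counts sum to the number of nodes.
#'
#' @param g An `interactome`.
#' @return A data frame with integer columns `k` and `count`, ascending in `k`.
#' @export
degree_histogram <- function(g) {
  stopifnot(inherits(g, "interactome"))
  deg <- igraph::degree(g$graph)
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Write an interactome as a two-column TSV edge list
#' @param g An `interactome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path) {
  stopifnot(inherits(g, "interactome"))
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  write_result_tsv(data.frame(symbol_a = el[, 1], symbol_b = el[, 2],
                              stringsAsFactors = FALSE), path)
}

#' Read an interactome from a two-column TSV edge list
#'
#' The file is assumed already clean (as written by
#' [write_interactome()]); self-loops and duplicates, if any, are
#' collapsed silently by the simple-graph constructor.
#'
#' @param path Path to a two-column TSV (`symbol_a`, `symbol_b`).
#' @return An object of class `interactome`.
#' @export
read_interactome <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("symbol_a", "symbol_b"), "interactome edge list")
  df$symbol_a <- normalize_symbols(df$symbol_a)
  df$symbol_b <- normalize_symbols(df$symbol_b)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  as_interactome(g)
}
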