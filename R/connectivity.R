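# The interconnectivity statistic: for a query node set, the fraction of
# its mapped members that lie in the largest connected component of the
# subgraph induced by the set. This is the core quantity of the analysis;
# components of the induced subgraph are found by breadth-first search
# over the induced edges only, which keeps each evaluation O(|E| + |S|)
# and makes the resampling null model cheap.

# Endpoint indices of all edges, computed once per graph and reused by
# the resampling loops.
edge_endpoints <- function(g) {
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  list(a = as.integer(el[, 1]), b = as.integer(el[, 2]),
       n = igraph::vcount(g$graph))
}

# Size of the largest connected component of the subgraph induced by the
# node indices `sampled`, given precomputed endpoints `ep` and a logical
# membership vector `member` (TRUE exactly at `sampled`). Isolated
# sampled nodes are components of size 1.
lcc_size_induced <- function(ep, member, sampled) {
  k <- length(sampled)
  if (k == 0L) return(0L)
  keep <- member[ep$a] & member[ep$b]
  if (!any(keep)) return(1L)
  a <- ep$a[keep]
  b <- ep$b[keep]
  local <- integer(ep$n)
  local[sampled] <- seq_len(k)
  la <- local[a]
  lb <- local[b]
  adj <- split(c(lb, la), factor(c(la, lb), levels = seq_len(k)))
  visited <- logical(k)
  queue <- integer(k)
  best <- 1L
  for (s in seq_len(k)) {
    if (visited[s]) next
    # breadth-first search from s over induced edges
    visited[s] <- TRUE
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nb <- adj[[v]]
      nb <- nb[!visited[nb]]
      ln <- length(nb)
      if (ln > 0L) {
        visited[nb] <- TRUE
        queue[(tail + 1L):(tail + ln)] <- nb
        tail <- tail + ln
      }
    }
    if (tail > best) best <- tail
  }
  best
}

#' Interconnectivity of a query set in the interactome
#'
#' Computes the fraction of the query's mapped symbols that fall in the
#' largest connected component of the subgraph induced by the query
#' (only edges with both endpoints in the query are considered). The
#' denominator is the number of query symbols present in the interactome
#' (`n_mapped`), not the raw query size, so unmapped symbols do not
#' dilute the statistic. Query symbols are de-duplicated and
#' case-normalized; a single mapped node is a (degenerate) connected
#' component of size 1, fraction 1. If nothing maps, the fraction is
#' reported as `NA` with a warning rather than an error.
#'
#' @param g An `interactome`.
#' @param query Character vector of protein symbols.
#' @return An object of class `interconnectivity`: list with `n_input`,
#'   `n_mapped`, `n_lcc`, `fraction`.
#' @export
largest_connected_fraction <- function(g, query) {
  stopifnot(inherits(g, "interactome"))
  query <- unique(normalize_symbols(query))
  query <- query[query != ""]
  if (length(query) == 0) stop("query is empty", call. = FALSE)
  idx <- match(query, igraph::V(g$graph)$name)
  idx <- idx[!is.na(idx)]
  n_mapped <- length(idx)
  if (n_mapped == 0) {
    warning("no query symbol maps to the interactome; fraction undefined",
            call. = FALSE)
    return(structure(list(n_input = length(query), n_mapped = 0L,
                          n_lcc = 0L, fraction = NA_real_),
                     class = "interconnectivity"))
  }
  ep <- edge_endpoints(g)
  member <- logical(ep$n)
  member[idx] <- TRUE
  n_lcc <- lcc_size_induced(ep, member, idx)
  structure(list(n_input = length(query), n_mapped = n_mapped,
                 n_lcc = n_lcc, fraction = n_lcc / n_mapped),
            class = "interconnectivity")
}

#' @export
print.interconnectivity <- function(x, ...) {
  cat(sprintf(
    "interconnectivity: %d/%d mapped symbols in the largest component (%.1f%%); %d submitted\n",
    x$n_lcc, x$n_mapped, 100 * x$fraction, x$n_input))
  invisible(x)
}

#' Interconnectivity result as a one-row data frame
#' @param x An `interconnectivity` object.
#' @param ... Unused.
#' @return One-row data frame (`n_input`, `n_mapped`, `n_lcc`, `fraction`).
#' @export
as.data.frame.interconnectivity <- function(x, ...) {
  data.frame(n_input = x$n_input, n_mapped = x$n_mapped,
             n_lcc = x$n_lcc, fraction = x$fraction)
}

#' Build a joint chemical-protein network
#'
#' Protein nodes are the targets of the listed chemicals at or above the
#' confidence threshold; PPI edges are the interactome edges induced
#' among those targets; chemical-target edges link each chemical to its
#' retained targets. The protein-side interconnectivity (ignoring
#' chemical connectivity) is available by passing `protein_nodes` to
#' [largest_connected_fraction()].
#'
#' @param g An `interactome`.
#' @param table Chemical-target data frame ([read_chem_targets()]).
#' @param chemicals Character vector of chemical IDs to include.
#' @param score_threshold Minimum `combined_score` on \[0, 1\]; default 0.4
#'   (medium stringency).
#' @return An object of class `joint_network`: list with
#'   `chemical_nodes`, `protein_nodes`, `ppi_edges` (two-column character
#'   matrix), `chem_target_edges` (data frame `chemical_id`, `protein`).
#' @export
build_joint_network <- function(g, table, chemicals, score_threshold = 0.4) {
  stopifnot(inherits(g, "interactome"),
            score_threshold >= 0, score_threshold <= 1)
  require_columns(table, c("chemical_id", "protein", "combined_score"),
                  "chemical-target table")
  rows <- table[table$chemical_id %in% chemicals &
                  table$combined_score >= score_threshold, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no chemical-target edge passes the threshold: empty joint network",
            call. = FALSE)
  }
  chem_edges <- unique(rows[, c("chemical_id", "protein")])
  rownames(chem_edges) <- NULL
  proteins <- sort(unique(chem_edges$protein))
  present <- intersect(proteins, igraph::V(g$graph)$name)
  ppi <- if (length(present) >= 2) {
    sub <- igraph::induced_subgraph(g$graph, present)
    igraph::as_edgelist(sub, names = TRUE)
  } else {
    matrix(character(0), ncol = 2)
  }
  structure(list(chemical_nodes = sort(unique(chem_edges$chemical_id)),
                 protein_nodes = proteins,
                 ppi_edges = ppi,
                 chem_target_edges = chem_edges),
            class = "joint_network")
}

#' @export
print.joint_network <- function(x, ...) {
  cat(sprintf(
    "joint network: %d chemicals, %d protein targets, %d PPI edges, %d chemical-target edges\n",
    length(x$chemical_nodes), length(x$protein_nodes),
    nrow(x$ppi_edges), nrow(x$chem_target_edges)))
  invisible(x)
}
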