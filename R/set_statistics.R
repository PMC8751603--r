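# Fisher-exact set-overlap tests against an explicit background
# universe, generic gene-set enrichment (hypergeometric with
# Benjamini-Hochberg correction), and ortholog-map filtering.

#' Fisher exact test for the overlap of two sets
#'
#' Builds the 2x2 table (overlap, A-only, B-only, neither) over an
#' explicit background universe and applies Fisher's exact test. The
#' default alternative is `"greater"` (enrichment). Members of A or B
#' absent from the universe are dropped with a message — backgrounds are
#' always explicit, never inferred.
#'
#' @param set_a,set_b Character vectors.
#' @param universe Character vector, the background; must be non-empty.
#' @param side `"greater"` (default) or `"two_sided"`.
#' @return An object of class `overlap_result`: list with `n_a`, `n_b`,
#'   `n_overlap`, `n_universe`, `odds_ratio` (conditional MLE; may be
#'   `Inf`), `p_value`, `test_side`.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           side = c("greater", "two_sided")) {
  side <- match.arg(side)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  out_a <- sum(!(set_a %in% universe))
  out_b <- sum(!(set_b %in% universe))
  if (out_a + out_b > 0) {
    message(out_a, " member(s) of A and ", out_b,
            " of B outside the universe dropped")
  }
  a <- intersect(set_a, universe)
  b <- intersect(set_b, universe)
  k <- length(intersect(a, b))
  n_a <- length(a)
  n_b <- length(b)
  n <- length(universe)
  tab <- matrix(c(k, n_a - k, n_b - k, n - n_a - n_b + k), nrow = 2)
  ft <- stats::fisher.test(tab, alternative = if (side == "greater")
    "greater" else "two.sided")
  structure(list(n_a = n_a, n_b = n_b, n_overlap = k, n_universe = n,
                 odds_ratio = unname(ft$estimate),
                 p_value = ft$p.value, test_side = side),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d of |A| = %d, |B| = %d in universe %d: OR = %.3g, p = %.3g (%s)\n",
    x$n_overlap, x$n_a, x$n_b, x$n_universe, x$odds_ratio, x$p_value,
    x$test_side))
  invisible(x)
}

#' Overlap result as a one-row data frame
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(n_a = x$n_a, n_b = x$n_b, n_overlap = x$n_overlap,
             n_universe = x$n_universe, odds_ratio = x$odds_ratio,
             p_value = x$p_value, test_side = x$test_side)
}

#' Gene-set enrichment of a query against a collection
#'
#' One hypergeometric (one-sided Fisher) test per set: with N the
#' universe size, K the set size, n the mapped query size and k the
#' query hits in the set, the p-value is P(X >= k) and the fold
#' enrichment is (k/n) / (K/N). p-values are Benjamini-Hochberg
#' adjusted across the collection. The optional EASE variant penalizes
#' single-hit sets by scoring k-1 hits instead of k; it is a reporting
#' option only, off by default.
#'
#' @param query Character vector of gene symbols.
#' @param collection A `gene_set_collection`.
#' @param ease Use the EASE-score variant (default `FALSE`).
#' @return Data frame with one row per set: `set_name`, `k`, `n`, `K`,
#'   `N`, `fold_enrichment`, `p_value`, `adjusted_p`; zero rows (with a
#'   warning) when the query misses the universe entirely.
#' @export
enrich <- function(query, collection, ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(normalize_symbols(query))
  mapped <- intersect(query, collection$universe)
  empty <- data.frame(set_name = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0))
  if (length(mapped) == 0) {
    warning("query does not intersect the collection universe",
            call. = FALSE)
    return(empty)
  }
  if (length(collection$sets) == 0) return(empty)
  N <- length(collection$universe)
  n <- length(mapped)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    K <- length(members)
    k <- length(intersect(mapped, members))
    k_eff <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               fold_enrichment = if (K > 0) (k / n) / (K / N) else 0,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' High-confidence view of an enrichment table
#'
#' The conventional reporting rule: adjusted p below a threshold and at
#' least a minimum fold enrichment, sorted by adjusted p.
#'
#' @param rows Data frame from [enrich()].
#' @param max_adjusted_p Adjusted-p cutoff (default 0.001).
#' @param min_fold Minimum fold enrichment (default 2).
#' @return Filtered, sorted data frame.
#' @export
enrich_filter <- function(rows, max_adjusted_p = 0.001, min_fold = 2) {
  require_columns(rows, c("adjusted_p", "fold_enrichment"), "enrichment table")
  out <- rows[rows$adjusted_p < max_adjusted_p &
                rows$fold_enrichment >= min_fold, , drop = FALSE]
  out <- out[order(out$adjusted_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control (via
#' [stats::p.adjust()]), capped at 1.
#'
#' @param p_values Non-empty numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values, in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values to adjust", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Filter an ortholog map by inparalog score
#'
#' Retains rows with `inparalog_score >= min_score` and de-duplicates
#' (source, target) pairs; one-to-many mappings are preserved.
#'
#' @param map Data frame from [read_ortholog_map()].
#' @param min_score Minimum score (the stringent convention is 1.0).
#' @return Data frame with columns `source_gene`, `target_gene`.
#' @export
filter_ortholog_map <- function(map, min_score = 1.0) {
  require_columns(map, c("source_gene", "target_gene", "inparalog_score"),
                  "ortholog map")
  out <- map[map$inparalog_score >= min_score,
             c("source_gene", "target_gene"), drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}
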