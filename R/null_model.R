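# Empirical resampling null model for interconnectivity. Random node
# subsets of a given size are drawn uniformly without replacement from
# the interactome (no degree matching), the interconnectivity of each is
# computed, and the mean and SD over replicates give a size-stratified
# expectation against which an observed set is scored as
# z = (observed - mean) / sd. Per-replicate seeds are derived
# deterministically from the master seed by a counter, so results do not
# depend on execution order and curves are reproducible.

#' Null distribution of interconnectivity at one sample size
#'
#' Draws `reps` uniform random subsets of `size` distinct nodes,
#' computes the largest-connected-component fraction of each, and
#' summarizes mean and standard deviation (unbiased, n-1 denominator).
#'
#' @param g An `interactome`.
#' @param size Subset size, between 2 and the node count.
#' @param reps Number of replicates (>= 2).
#' @param seed Master seed; replicate i uses a seed derived from
#'   (`seed`, i).
#' @return An object of class `null_point`: list with `sample_size`,
#'   `reps`, `mean_fraction`, `sd_fraction` and the raw `fractions`.
#' @export
sample_null_fraction <- function(g, size, reps, seed) {
  stopifnot(inherits(g, "interactome"), reps >= 2)
  n <- igraph::vcount(g$graph)
  if (size < 2 || size > n) {
    stop("sample size must be between 2 and the interactome node count (",
         n, ")", call. = FALSE)
  }
  ep <- edge_endpoints(g)
  fractions <- numeric(reps)
  member <- logical(n)
  for (i in seq_len(reps)) {
    set.seed(derive_seed(seed, "replicate", i))
    s <- sample.int(n, size)
    member[s] <- TRUE
    fractions[i] <- lcc_size_induced(ep, member, s) / size
    member[s] <- FALSE
  }
  structure(list(sample_size = as.integer(size), reps = as.integer(reps),
                 mean_fraction = mean(fractions),
                 sd_fraction = stats::sd(fractions),
                 fractions = fractions),
            class = "null_point")
}

#' @export
print.null_point <- function(x, ...) {
  cat(sprintf("null interconnectivity at size %d (%d reps): %.4f +/- %.4f\n",
              x$sample_size, x$reps, x$mean_fraction, x$sd_fraction))
  invisible(x)
}

#' Expected-interconnectivity curve over a grid of sample sizes
#'
#' Evaluates [sample_null_fraction()] at sizes `min_size`,
#' `min_size + step`, ... up to `max_size`. The conventional grid starts
#' at 50 because the interconnectivity of very small node sets is highly
#' variable. Per-point seeds are derived from the master seed and the
#' size, so adding grid points never perturbs existing ones.
#'
#' @param g An `interactome`.
#' @param min_size,max_size,step Integer grid (step > 0).
#' @param reps Replicates per grid point (default 100).
#' @param seed Master seed.
#' @return Data frame with columns `sample_size`, `reps`,
#'   `mean_fraction`, `sd_fraction`; zero rows (with a warning) when
#'   `max_size < min_size`.
#' @export
null_curve <- function(g, min_size = 50, max_size, step = 50, reps = 100,
                       seed) {
  stopifnot(inherits(g, "interactome"), min_size >= 2)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (max_size < min_size) {
    warning("max_size < min_size: empty null curve", call. = FALSE)
    return(data.frame(sample_size = integer(0), reps = integer(0),
                      mean_fraction = numeric(0), sd_fraction = numeric(0)))
  }
  sizes <- seq(from = min_size, to = max_size, by = step)
  rows <- lapply(sizes, function(s) {
    pt <- sample_null_fraction(g, s, reps, derive_seed(seed, "size", s))
    data.frame(sample_size = pt$sample_size, reps = pt$reps,
               mean_fraction = pt$mean_fraction,
               sd_fraction = pt$sd_fraction)
  })
  do.call(rbind, rows)
}

#' z-score of an observed set against the size-matched null
#'
#' Computes the observed interconnectivity of `query`, then the null
#' distribution at the same sample size (the number of mapped query
#' symbols, so observed and null statistics share a denominator
#' convention), and the z-score (observed - mean) / sd. A degenerate
#' null with zero SD yields a missing z with a warning.
#'
#' @param g An `interactome`.
#' @param query Character vector of protein symbols (>= 2 must map).
#' @param reps Null replicates (default 1000).
#' @param seed Master seed.
#' @return An object of class `null_summary`: list with `sample_size`,
#'   `reps`, `mean_fraction`, `sd_fraction`, `observed_fraction`,
#'   `z_score` and the embedded `observed` interconnectivity result.
#' @export
z_for_observed <- function(g, query, reps = 1000, seed) {
  obs <- largest_connected_fraction(g, query)
  if (obs$n_mapped < 2) {
    stop("query must map to at least 2 interactome nodes", call. = FALSE)
  }
  null <- sample_null_fraction(g, obs$n_mapped, reps, seed)
  z <- if (null$sd_fraction == 0) {
    warning("null SD is zero; z-score undefined", call. = FALSE)
    NA_real_
  } else {
    (obs$fraction - null$mean_fraction) / null$sd_fraction
  }
  structure(list(sample_size = obs$n_mapped, reps = as.integer(reps),
                 mean_fraction = null$mean_fraction,
                 sd_fraction = null$sd_fraction,
                 observed_fraction = obs$fraction,
                 z_score = z, observed = obs),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "observed interconnectivity %.4f vs null %.4f +/- %.4f at size %d (%d reps): z = %s\n",
    x$observed_fraction, x$mean_fraction, x$sd_fraction, x$sample_size,
    x$reps, ifelse(is.na(x$z_score), "NA", sprintf("%.2f", x$z_score))))
  invisible(x)
}

#' Null summary as a one-row data frame
#' @param x A `null_summary` object.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.null_summary <- function(x, ...) {
  data.frame(sample_size = x$sample_size, reps = x$reps,
             mean_fraction = x$mean_fraction, sd_fraction = x$sd_fraction,
             observed_fraction = x$observed_fraction, z_score = x$z_score)
}
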