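# Scale-free topology: fit P(k) = a * k^b to a degree histogram by
# ordinary least squares on the log-log scale, the way network-viewer
# degree-distribution regressions report it (P(k) is the raw node count
# at degree k, not a normalized probability, so the coefficient can be
# much larger than 1). A maximum-likelihood tail fit is available as a
# clearly separate optional diagnostic.

#' Fit a power law to a degree histogram
#'
#' Ordinary least squares of log10(count) on log10(k), over all degrees
#' k >= 1 with a positive count; degree-0 nodes are excluded (their log
#' is undefined) with a message. The fitted model is
#' P(k) = coefficient * k^exponent with coefficient = 10^intercept and
#' exponent = slope (typically negative for heavy-tailed networks).
#'
#' @param hist Data frame with columns `k` and `count`
#'   ([degree_histogram()]), or a named vector (names = degrees).
#' @return An object of class `power_law_fit`: list with `coefficient`,
#'   `exponent`, `r_squared`, `k_range` (min/max degree used) and
#'   `n_points`.
#' @export
fit_power_law <- function(hist) {
  if (!is.data.frame(hist)) {
    hist <- data.frame(k = as.integer(names(hist)),
                       count = as.numeric(hist))
  }
  require_columns(hist, c("k", "count"), "degree histogram")
  if (any(hist$k == 0 & hist$count > 0)) {
    message("degree-0 nodes excluded from the power-law fit")
  }
  pts <- hist[hist$k >= 1 & hist$count > 0, , drop = FALSE]
  if (nrow(pts) < 3) {
    stop("degenerate degree distribution: fewer than 3 usable (k, P(k)) points",
         call. = FALSE)
  }
  fit <- stats::lm(log10(count) ~ log10(k), data = pts)
  co <- stats::coef(fit)
  structure(list(coefficient = unname(10^co[1]),
                 exponent = unname(co[2]),
                 r_squared = summary(fit)$r.squared,
                 k_range = c(min(pts$k), max(pts$k)),
                 n_points = nrow(pts)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: P(k) = %.3g * k^%.3f (R^2 = %.4f; %d points, k in [%d, %d])\n",
    x$coefficient, x$exponent, x$r_squared, x$n_points,
    x$k_range[1], x$k_range[2]))
  invisible(x)
}

#' Maximum-likelihood power-law exponent (optional diagnostic)
#'
#' A discrete maximum-likelihood tail fit of the degree sequence,
#' delegated to [igraph::fit_power_law()]. This is a different estimator
#' from the log-log regression of [fit_power_law()] (it models the tail
#' beyond `xmin` and reports a positive alpha for P(k) ~ k^-alpha); the
#' two are reported side by side, never mixed.
#'
#' @param g An `interactome`.
#' @param xmin Lower degree bound for the tail fit (`NULL` = estimated).
#' @return List with `alpha`, `xmin`, `log_likelihood`.
#' @export
power_law_ml <- function(g, xmin = NULL) {
  stopifnot(inherits(g, "interactome"))
  deg <- igraph::degree(g$graph)
  deg <- deg[deg >= 1]
  fit <- igraph::fit_power_law(deg, xmin = if (is.null(xmin)) NA else xmin,
                               implementation = "plfit")
  list(alpha = fit$alpha, xmin = fit$xmin, log_likelihood = fit$logLik)
}
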