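# End-to-end orchestration: one config drives cleaning, target
# aggregation, interconnectivity + null z-scores, topology, enrichment
# and the cocktail report. Every stage draws its seed deterministically
# from the master seed keyed by stage name, so adding a stage never
# perturbs the randomness of earlier ones, and reruns are byte-identical.

#' Build and validate a pipeline run configuration
#'
#' @param graph Path to an edge-list file.
#' @param graph_dialect Dialect for [read_edge_list()].
#' @param taxon Taxonomy ID to keep when cleaning.
#' @param chem_targets Path to a chemical-target TSV.
#' @param score_scale Score scale for [read_chem_targets()].
#' @param score_threshold Confidence cutoff (default 0.4).
#' @param gmt Optional path to a GMT collection.
#' @param tf_table Optional path to a TF-target TSV.
#' @param tfs TF symbols for the cocktail/TF overlap (used with
#'   `tf_table`).
#' @param cocktail_defs Optional path to cocktail definitions (default:
#'   the packaged ten cocktails).
#' @param sm_catalog_path Optional path to an SM catalog.
#' @param reps_curve Replicates per null-curve point (default 100).
#' @param reps_significance Replicates for z-scores (default 1000).
#' @param curve_min,curve_step Null-curve grid (default 50/50); the grid
#'   top is the interactome size. `curve_min = NULL` skips the curve.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(graph, graph_dialect = "simple_tsv", taxon = 9606,
                       chem_targets, score_scale = "unit",
                       score_threshold = 0.4, gmt = NULL,
                       tf_table = NULL, tfs = NULL,
                       cocktail_defs = NULL, sm_catalog_path = NULL,
                       reps_curve = 100, reps_significance = 1000,
                       curve_min = 50, curve_step = 50,
                       seed = 1, out_dir) {
  stopifnot(reps_curve >= 2, reps_significance >= 2,
            score_threshold >= 0, score_threshold <= 1)
  for (p in c(graph, chem_targets, gmt, tf_table, cocktail_defs,
              sm_catalog_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("config path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(graph = graph, graph_dialect = graph_dialect,
                 taxon = taxon, chem_targets = chem_targets,
                 score_scale = score_scale,
                 score_threshold = score_threshold, gmt = gmt,
                 tf_table = tf_table, tfs = tfs,
                 cocktail_defs = cocktail_defs,
                 sm_catalog_path = sm_catalog_path,
                 reps_curve = reps_curve,
                 reps_significance = reps_significance,
                 curve_min = curve_min, curve_step = curve_step,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read and clean the interactome; (2) read chemical-target
#' rows and aggregate the full target set at the confidence threshold;
#' (3) observed interconnectivity and z-score against the resampling
#' null; (4) null expectation curve over sample sizes (optional);
#' (5) power-law fit of the degree distribution of the target-induced
#' subgraph; (6) gene-set enrichment of the target set (optional);
#' (7) per-cocktail report: membership summaries, aggregated targets,
#' interconnectivity, z-score, and overlap with TF targets (optional).
#' Writes TSV tables plus a JSON run report (version, config echo,
#' per-stage counts, cleaning provenance) to `out_dir` and returns the
#' report invisibly.
#'
#' @param config A `run_config`.
#' @return The run report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("reprognet")),
                 config = config[setdiff(names(config), c("tfs", "out_dir"))],
                 stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # 1: interactome
  g <- stage("interactome", {
    records <- read_edge_list(config$graph, config$graph_dialect)
    clean_interactome(records, config$taxon)
  })
  report$stages$interactome <- list(
    nodes = igraph::vcount(g$graph), edges = igraph::ecount(g$graph),
    removed = as.list(g$provenance))

  # 2: targets
  chem <- stage("chem_targets",
                read_chem_targets(config$chem_targets, config$score_scale))
  all_chemicals <- unique(chem$chemical_id)
  targets <- stage("chem_targets",
                   aggregate_targets(all_chemicals, chem,
                                     config$score_threshold))
  report$stages$targets <- list(n_chemicals = length(all_chemicals),
                                n_rows = nrow(chem),
                                n_targets = length(targets))

  # 3: interconnectivity + z
  zsum <- stage("interconnectivity",
                z_for_observed(g, targets, config$reps_significance,
                               derive_seed(config$seed, "significance")))
  write_result_tsv(as.data.frame(zsum),
                   file.path(config$out_dir, "interconnectivity.tsv"))
  report$stages$interconnectivity <- as.list(as.data.frame(zsum))

  # 4: null curve
  if (!is.null(config$curve_min)) {
    curve <- stage("null_curve",
                   null_curve(g, min_size = config$curve_min,
                              max_size = igraph::vcount(g$graph),
                              step = config$curve_step,
                              reps = config$reps_curve,
                              seed = derive_seed(config$seed, "curve")))
    write_result_tsv(curve, file.path(config$out_dir, "null_curve.tsv"))
    report$stages$null_curve <- list(n_points = nrow(curve))
  }

  # 5: topology of the target-induced subgraph
  mapped <- intersect(targets, interactome_nodes(g))
  topo <- stage("topology", {
    sub <- as_interactome(igraph::induced_subgraph(g$graph, mapped))
    hist <- degree_histogram(sub)
    write_result_tsv(hist,
                     file.path(config$out_dir, "target_degree_histogram.tsv"))
    tryCatch(fit_power_law(hist), error = function(e) NULL)
  })
  report$stages$topology <- if (is.null(topo)) {
    list(fit = "degenerate degree distribution")
  } else {
    list(coefficient = topo$coefficient, exponent = topo$exponent,
         r_squared = topo$r_squared, n_points = topo$n_points,
         k_range = topo$k_range)
  }

  # 6: enrichment
  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", {
      collection <- read_gmt(config$gmt)
      enrich(targets, collection)
    })
    write_result_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
    report$stages$enrichment <- list(
      n_sets = nrow(enr),
      n_significant = nrow(enrich_filter(enr)))
  }

  # 7: cocktails
  catalog <- stage("cocktails", sm_catalog(config$sm_catalog_path))
  defs <- stage("cocktails",
                cocktail_definitions(config$cocktail_defs, catalog))
  write_result_tsv(sm_frequency(defs),
                   file.path(config$out_dir, "sm_frequency.tsv"))
  tf_df <- if (!is.null(config$tf_table)) {
    stage("cocktails", read_tf_targets(config$tf_table))
  }
  universe <- if (!is.null(tf_df)) {
    intersect(unique(chem$protein), unique(tf_df$target))
  }
  cocktail_rows <- lapply(names(defs), function(nm) {
    members <- defs[[nm]]
    ctargets <- suppressWarnings(
      aggregate_targets(members, chem, config$score_threshold))
    row <- data.frame(cocktail = nm, n_members = length(members),
                      covers_core = covers_core_categories(members, catalog),
                      n_targets = length(ctargets),
                      n_mapped = NA_integer_, fraction = NA_real_,
                      z_score = NA_real_, tf_overlap_p = NA_real_,
                      stringsAsFactors = FALSE)
    mapped_c <- intersect(ctargets, interactome_nodes(g))
    if (length(mapped_c) >= 2) {
      zs <- z_for_observed(g, ctargets, config$reps_significance,
                           derive_seed(config$seed, "cocktail", nm))
      row$n_mapped <- zs$sample_size
      row$fraction <- zs$observed_fraction
      row$z_score <- zs$z_score
    }
    if (!is.null(tf_df) && !is.null(config$tfs) &&
        length(intersect(ctargets, universe)) >= 0 && length(universe) > 0) {
      ov <- tryCatch(
        compare_to_tf_targets(ctargets, tf_df, config$tfs, universe),
        error = function(e) NULL)
      if (!is.null(ov)) row$tf_overlap_p <- ov$p_value
    }
    row
  })
  cocktail_tab <- do.call(rbind, cocktail_rows)
  write_result_tsv(cocktail_tab,
                   file.path(config$out_dir, "cocktail_summary.tsv"))
  report$stages$cocktails <- list(
    n_cocktails = length(defs),
    n_nonredundant_sms = length(cocktail_union(defs)),
    all_cover_core = all(cocktail_tab$covers_core))

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
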