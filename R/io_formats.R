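# Readers and writers for the external file dialects consumed by the
# pipeline: interaction edge lists (BioGRID-TAB-like or a compact TSV),
# STITCH-like chemical-protein tables, GMT gene-set collections,
# TF->target tables and precomputed ortholog maps. Parsers validate and
# normalize; they never filter (cleaning is a separate, provenance-counted
# step in clean_interactome()).

.BIOGRID_COLS <- c(symbol_a = "Official Symbol Interactor A",
                   symbol_b = "Official Symbol Interactor B",
                   system_type = "Experimental System Type",
                   organism_a = "Organism Interactor A",
                   organism_b = "Organism Interactor B")

.SIMPLE_COLS <- c(symbol_a = "symbol_a", symbol_b = "symbol_b",
                  system_type = "system_type",
                  organism_a = "organism_a", organism_b = "organism_b")

#' Read a protein-protein interaction edge list
#'
#' Parses either a BioGRID TAB-like file (official symbol, experimental
#' system type and organism columns) or a compact five-column TSV
#' (`symbol_a`, `symbol_b`, `system_type`, `organism_a`, `organism_b`).
#' Symbols are upper-cased and whitespace-stripped. Every data row is
#' either parsed or rejected with a row-number diagnostic; no biological
#' filtering happens here — self-loops, duplicates, genetic interactions
#' and off-species rows are all retained for [clean_interactome()].
#'
#' @param path Path to a tab-separated file; `#`-prefixed lines ignored.
#' @param dialect `"simple_tsv"` or `"biogrid_tab"`.
#' @return A data frame of edge records with columns `symbol_a`,
#'   `symbol_b`, `system_type` (`"physical"` or `"genetic"`),
#'   `organism_a`, `organism_b` (integer NCBI taxonomy IDs).
#' @seealso [clean_interactome()]
#' @export
read_edge_list <- function(path, dialect = c("simple_tsv", "biogrid_tab")) {
  dialect <- match.arg(dialect)
  raw <- read_tsv_file(path)
  cols <- if (dialect == "biogrid_tab") .BIOGRID_COLS else .SIMPLE_COLS
  require_columns(raw, unname(cols), sprintf("edge list (%s)", dialect))
  df <- data.frame(symbol_a = normalize_symbols(raw[[cols["symbol_a"]]]),
                   symbol_b = normalize_symbols(raw[[cols["symbol_b"]]]),
                   system_type = tolower(trimws(raw[[cols["system_type"]]])),
                   organism_a = suppressWarnings(as.integer(raw[[cols["organism_a"]]])),
                   organism_b = suppressWarnings(as.integer(raw[[cols["organism_b"]]])),
                   stringsAsFactors = FALSE)
  bad_sym <- which(df$symbol_a == "" | df$symbol_b == "")
  if (length(bad_sym) > 0) {
    stop("edge list: empty interactor symbol at data row(s) ",
         paste(bad_sym, collapse = ", "), call. = FALSE)
  }
  bad_type <- which(!(df$system_type %in% c("physical", "genetic")))
  if (length(bad_type) > 0) {
    stop("edge list: unknown system_type ",
         paste(unique(df$system_type[bad_type]), collapse = ", "),
         " at data row(s) ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  bad_org <- which(is.na(df$organism_a) | is.na(df$organism_b))
  if (length(bad_org) > 0) {
    stop("edge list: non-integer organism ID at data row(s) ",
         paste(bad_org, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an edge list as a simple TSV
#'
#' @param records Data frame as returned by [read_edge_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(records, path) {
  require_columns(records, unname(.SIMPLE_COLS), "edge records")
  write_result_tsv(records[, unname(.SIMPLE_COLS)], path)
}

.CHANNELS <- c("experimental", "database", "textmining", "prediction")

#' Read a STITCH-like chemical-protein interaction table
#'
#' Expects columns `chemical_id`, `protein`, the four evidence channels
#' (`experimental`, `database`, `textmining`, `prediction`) and
#' `combined_score`. Scores may be on the native STITCH thousandths scale
#' (0-1000) or already on the unit scale; either way they are stored on
#' \[0, 1\] so that the conventional medium-stringency cutoff 0.4 can be
#' used literally downstream.
#'
#' @param path Path to a tab-separated file.
#' @param score_scale `"thousandths"` (divide by 1000) or `"unit"`.
#' @return A data frame with all scores on \[0, 1\]; zero rows (with a
#'   warning) for an empty table.
#' @export
read_chem_targets <- function(path, score_scale = c("thousandths", "unit")) {
  score_scale <- match.arg(score_scale)
  raw <- read_tsv_file(path)
  score_cols <- c(.CHANNELS, "combined_score")
  require_columns(raw, c("chemical_id", "protein", score_cols),
                  "chemical-target table")
  if (nrow(raw) == 0) {
    warning("chemical-target table is empty: ", path, call. = FALSE)
  }
  df <- raw[, c("chemical_id", "protein", score_cols)]
  df$chemical_id <- trimws(as.character(df$chemical_id))
  df$protein <- normalize_symbols(df$protein)
  bad_id <- which(df$chemical_id == "" | df$protein == "")
  if (length(bad_id) > 0) {
    stop("chemical-target table: empty chemical_id or protein at data row(s) ",
         paste(bad_id, collapse = ", "), call. = FALSE)
  }
  hi <- if (score_scale == "thousandths") 1000 else 1
  for (col in score_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0 | v > hi)
    if (length(bad) > 0) {
      stop(sprintf(
        "chemical-target table: score '%s' outside [0, %g] at data row(s) %s",
        col, hi, paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v / hi
  }
  df
}

#' Write a chemical-target table (unit-scale scores) as TSV
#'
#' @param table Data frame as returned by [read_chem_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chem_targets <- function(table, path) {
  require_columns(table, c("chemical_id", "protein", .CHANNELS, "combined_score"),
                  "chemical-target table")
  write_result_tsv(table, path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then one or more member symbols. Members are upper-cased and
#' de-duplicated. The universe defaults to the union of all members; if
#' supplied explicitly, members outside it are dropped with a message so
#' the invariant "every member belongs to the universe" always holds.
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector of background symbols.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[fields != "" | seq_along(fields) <= 2]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      stop("duplicate gene-set name '", nm, "' at GMT line ", i, call. = FALSE)
    }
    sets[[nm]] <- unique(normalize_symbols(fields[-(1:2)]))
  }
  gene_set_collection(sets, universe)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param universe Optional explicit background; defaults to the union of
#'   all set members. Members outside an explicit universe are dropped
#'   with a message.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    stop("gene sets must have unique names", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(normalize_symbols(s)))
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- members
  } else {
    universe <- unique(normalize_symbols(universe))
    outside <- setdiff(members, universe)
    if (length(outside) > 0) {
      message(length(outside),
              " set member(s) outside the declared universe dropped")
      sets <- lapply(sets, function(s) intersect(s, universe))
    }
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read a transcription-factor target table
#'
#' Two required columns, `tf` and `target` (TRRUST-like). Duplicate
#' (tf, target) pairs are collapsed with a message.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame with columns `tf` and `target`.
#' @export
read_tf_targets <- function(path) {
  raw <- read_tsv_file(path)
  require_columns(raw, c("tf", "target"), "TF-target table")
  df <- data.frame(tf = normalize_symbols(raw$tf),
                   target = normalize_symbols(raw$target),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    message(sum(dup), " duplicate (tf, target) pair(s) collapsed")
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a precomputed ortholog map
#'
#' Columns `source_gene`, `target_gene`, `inparalog_score` (scores on
#' \[0, 1\]). The map is consumed as-is; score filtering is a separate
#' step ([filter_ortholog_map()]).
#'
#' @param path Path to a tab-separated file.
#' @return A data frame of ortholog pairs with scores.
#' @export
read_ortholog_map <- function(path) {
  raw <- read_tsv_file(path)
  require_columns(raw, c("source_gene", "target_gene", "inparalog_score"),
                  "ortholog map")
  df <- data.frame(source_gene = normalize_symbols(raw$source_gene),
                   target_gene = normalize_symbols(raw$target_gene),
                   inparalog_score = suppressWarnings(as.numeric(raw$inparalog_score)),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$inparalog_score) | df$inparalog_score < 0 |
                 df$inparalog_score > 1)
  if (length(bad) > 0) {
    stop("ortholog map: inparalog_score outside [0, 1] at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}
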