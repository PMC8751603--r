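# SM cocktail combinatorics: the catalog of non-redundant reprogramming
# small molecules (with synonyms and bioactivity categories), the ten
# published cocktail compositions, name canonicalization, union /
# frequency / category-coverage summaries, per-cocktail target
# aggregation and comparison against transcription-factor target sets.

.split_multi <- function(x) {
  lapply(strsplit(as.character(x), "|", fixed = TRUE),
         function(v) trimws(v[trimws(v) != ""]))
}

#' Catalog of non-redundant reprogramming small molecules
#'
#' The 22 SMs appearing across the ten published reprogramming
#' cocktails, with synonyms, bioactivity and functional categories
#' (epigenetic / signaling / metabolic / other; an SM may carry more
#' than one). Shipped as a plain-text fixture in `extdata`.
#'
#' @param path Optional path to an alternative catalog TSV with columns
#'   `canonical_name`, `synonyms` (|-separated), `categories`
#'   (|-separated), `bioactivity`.
#' @return Data frame with list-columns `synonyms` and `categories`.
#' @export
sm_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sm_catalog.tsv", package = "reprognet",
                        mustWork = TRUE)
  }
  raw <- read_tsv_file(path)
  require_columns(raw, c("canonical_name", "synonyms", "categories",
                         "bioactivity"), "SM catalog")
  df <- data.frame(canonical_name = trimws(raw$canonical_name),
                   bioactivity = trimws(raw$bioactivity),
                   stringsAsFactors = FALSE)
  df$synonyms <- .split_multi(raw$synonyms)
  df$categories <- .split_multi(raw$categories)
  if (anyDuplicated(df$canonical_name)) {
    stop("duplicate canonical_name in SM catalog", call. = FALSE)
  }
  bad_cat <- setdiff(unlist(df$categories),
                     c("epigenetic", "signaling", "metabolic", "other"))
  if (length(bad_cat) > 0) {
    stop("unknown SM category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  keys <- c(tolower(df$canonical_name), tolower(unlist(df$synonyms)))
  if (anyDuplicated(keys)) {
    stop("SM catalog names/synonyms are not disjoint: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Canonicalize small-molecule names
#'
#' Case-insensitive match of each name against the catalog's canonical
#' names and synonyms. Unknown names raise an error listing the nearest
#' catalog entries (by edit distance).
#'
#' @param names Character vector of SM names as written.
#' @param catalog Catalog data frame ([sm_catalog()]).
#' @return Character vector of canonical names.
#' @export
canonicalize <- function(names, catalog = sm_catalog()) {
  key <- tolower(trimws(names))
  lookup <- c(stats::setNames(catalog$canonical_name,
                              tolower(catalog$canonical_name)),
              stats::setNames(rep(catalog$canonical_name,
                                  lengths(catalog$synonyms)),
                              tolower(unlist(catalog$synonyms))))
  hit <- lookup[key]
  if (anyNA(hit)) {
    unknown <- unique(names[is.na(hit)])
    nearest <- vapply(tolower(unknown), function(u) {
      d <- utils::adist(u, names(lookup))
      paste(unique(lookup[order(d)][1:3]), collapse = ", ")
    }, character(1))
    stop("unknown SM name(s): ",
         paste(sprintf("'%s' (nearest: %s)", unknown, nearest),
               collapse = "; "), call. = FALSE)
  }
  unname(hit)
}

#' The ten published SM reprogramming cocktails
#'
#' Loads the packaged cocktail compositions (or an alternative file with
#' columns `cocktail`, `label`, `member`), canonicalizes every member
#' against the catalog and de-duplicates within each cocktail.
#'
#' @param path Optional path to an alternative definitions TSV.
#' @param catalog Catalog data frame ([sm_catalog()]).
#' @return Named list of character vectors of canonical SM names, with a
#'   `labels` attribute carrying each cocktail's published shorthand.
#' @export
cocktail_definitions <- function(path = NULL, catalog = sm_catalog()) {
  if (is.null(path)) {
    path <- system.file("extdata", "cocktails.tsv", package = "reprognet",
                        mustWork = TRUE)
  }
  raw <- read_tsv_file(path)
  require_columns(raw, c("cocktail", "label", "member"),
                  "cocktail definitions")
  raw$member <- canonicalize(raw$member, catalog)
  split_members <- split(raw$member, raw$cocktail)
  labels <- vapply(split(raw$label, raw$cocktail), function(l) l[1],
                   character(1))
  # preserve file order of cocktails
  ord <- unique(raw$cocktail)
  defs <- lapply(split_members[ord], unique)
  if (any(lengths(defs) == 0)) stop("empty cocktail definition", call. = FALSE)
  attr(defs, "labels") <- labels[ord]
  defs
}

#' Union of cocktail member sets
#'
#' @param cocktails Named list of canonical member vectors.
#' @return Sorted character vector of non-redundant SM names.
#' @export
cocktail_union <- function(cocktails) {
  sort(unique(as.character(unlist(cocktails, use.names = FALSE))))
}

#' Per-SM cocktail frequency
#'
#' Counts, for every SM, the number of cocktails containing it, sorted
#' by descending count and then name.
#'
#' @param cocktails Named list of canonical member vectors.
#' @return Data frame with columns `sm` and `n_cocktails`.
#' @export
sm_frequency <- function(cocktails) {
  members <- unlist(lapply(cocktails, unique), use.names = FALSE)
  if (length(members) == 0) {
    return(data.frame(sm = character(0), n_cocktails = integer(0)))
  }
  tab <- table(members)
  out <- data.frame(sm = names(tab), n_cocktails = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_cocktails, out$sm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category coverage of a cocktail
#'
#' Counts cocktail members per functional category (an SM carrying two
#' categories counts in both).
#'
#' @param members Character vector of canonical SM names.
#' @param catalog Catalog data frame ([sm_catalog()]).
#' @return Named integer vector over `epigenetic`, `signaling`,
#'   `metabolic`, `other`.
#' @export
category_coverage <- function(members, catalog = sm_catalog()) {
  idx <- match(unique(members), catalog$canonical_name)
  if (anyNA(idx)) {
    stop("cocktail member(s) not in catalog: ",
         paste(unique(members)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cats <- unlist(catalog$categories[idx])
  all_cats <- c("epigenetic", "signaling", "metabolic", "other")
  counts <- stats::setNames(integer(4), all_cats)
  tab <- table(cats)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Does a cocktail cover all three core activity categories?
#'
#' TRUE when the cocktail has at least one epigenetic, one signaling and
#' one metabolic member — the composition rule shared by all published
#' reprogramming cocktails.
#'
#' @inheritParams category_coverage
#' @return Logical scalar.
#' @export
covers_core_categories <- function(members, catalog = sm_catalog()) {
  cov <- category_coverage(members, catalog)
  all(cov[c("epigenetic", "signaling", "metabolic")] >= 1)
}

#' Aggregate the protein targets of a cocktail
#'
#' Union over cocktail members of chemical-target rows at or above the
#' confidence threshold (default 0.4, medium stringency). Chemical IDs
#' in the table are matched case-insensitively against member names.
#'
#' @param members Character vector of canonical SM names.
#' @param table Chemical-target data frame ([read_chem_targets()]).
#' @param threshold Minimum `combined_score` on \[0, 1\].
#' @return Sorted character vector of protein symbols (empty, with a
#'   warning, if nothing passes).
#' @export
aggregate_targets <- function(members, table, threshold = 0.4) {
  stopifnot(threshold >= 0, threshold <= 1)
  require_columns(table, c("chemical_id", "protein", "combined_score"),
                  "chemical-target table")
  rows <- table[tolower(table$chemical_id) %in% tolower(members) &
                  table$combined_score >= threshold, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no target passes the threshold for this cocktail",
            call. = FALSE)
    return(character(0))
  }
  sort(unique(rows$protein))
}

#' Overlap of cocktail targets with transcription-factor targets
#'
#' Restricts both sets to the declared universe (conventionally, the
#' genes present in both the chemical-target and the TF-target source),
#' takes the targets of the given TFs from the table, and tests the
#' overlap with a one-sided Fisher exact test.
#'
#' @param cocktail_targets Character vector of protein symbols.
#' @param tf_table TF-target data frame ([read_tf_targets()]).
#' @param tfs Character vector of TF symbols (e.g. the four canonical
#'   pluripotency factors).
#' @param universe Character vector, the background.
#' @return An `overlap_result` (see [fisher_overlap()]).
#' @export
compare_to_tf_targets <- function(cocktail_targets, tf_table, tfs, universe) {
  require_columns(tf_table, c("tf", "target"), "TF-target table")
  tfs <- unique(normalize_symbols(tfs))
  universe <- unique(normalize_symbols(universe))
  tf_targets <- unique(normalize_symbols(
    tf_table$target)[normalize_symbols(tf_table$tf) %in% tfs])
  tf_targets <- intersect(tf_targets, universe)
  if (length(tf_targets) == 0) {
    stop("no TF target remains after restriction to the universe",
         call. = FALSE)
  }
  fisher_overlap(intersect(normalize_symbols(cocktail_targets), universe),
                 tf_targets, universe, side = "greater")
}

#' SMs found in the human metabolome
#'
#' The packaged table of reprogramming SMs that are also human
#' metabolites, with role (inducer/enhancer) and chemical class.
#'
#' @return Data frame with columns `name`, `role`, `chemical_class`.
#' @export
sm_metabolites <- function() {
  path <- system.file("extdata", "sm_metabolites.tsv",
                      package = "reprognet", mustWork = TRUE)
  read_tsv_file(path)
}
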