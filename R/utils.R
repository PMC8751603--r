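# Internal helpers shared across modules.

# Deterministic 31-bit seed derivation: master seed + arbitrary keys
# (strings/integers) -> child seed. Linear congruential mixing over the
# byte stream; exact in double arithmetic (all intermediates < 2^53).
derive_seed <- function(master, ...) {
  keys <- list(...)
  h <- as.numeric(master) %% 2147483647
  feed <- function(h, bytes) {
    for (b in bytes) h <- (h * 69069 + b + 1) %% 2147483647
    h
  }
  for (k in keys) {
    if (is.character(k)) {
      h <- feed(h, utf8ToInt(paste(k, collapse = "\r")))
    } else {
      h <- feed(h, as.numeric(k) %% 2147483647)
    }
  }
  as.integer(h %% 2147483562 + 1)
}

normalize_symbols <- function(x) toupper(trimws(as.character(x)))

# Tab-separated reader used by all loaders: UTF-8, '#' comment lines ignored.
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Write a result table as TSV
#'
#' Plain tab-separated output with a header row, no quoting and no row
#' names, so that tables round-trip through the package's readers.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
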