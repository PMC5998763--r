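# Shared TSV dialect: tab-separated, UTF-8, header row required, "." = missing.

#' Read a TSV table in the package dialect
#'
#' @param path file path.
#' @param required_cols character vector of columns that must be present.
#' @return data.frame with character columns; "." converted to NA.
#' @keywords internal
read_tsv <- function(path, required_cols = character()) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character",
                   na.strings = ".", fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a TSV table in the package dialect
#'
#' Numeric columns are formatted with up to 10 significant digits so that
#' identical in-memory values always serialize to identical bytes.
#'
#' @param df data.frame.
#' @param path output path.
#' @keywords internal
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- formatC(out[[j]], digits = 10, format = "g")
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

# Identifier hygiene: strip surrounding whitespace, compare case-sensitively.
normalize_id <- function(x) {
  trimws(as.character(x))
}

#' Normalize a free-text phenotype/indication term
#'
#' Lowercase, strip punctuation, collapse whitespace. Used on both sides of
#' the indication match so vocabularies agree; no ontology expansion.
#'
#' @param x character vector of terms.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Stable pair key used to index feature rows.
pair_key <- function(a, b) paste(a, b, sep = "\r")
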