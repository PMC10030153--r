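#' @importFrom utils read.delim write.table packageVersion
NULL

#' Read a tab-delimited annotation table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used
#' throughout the package: UTF-8, header row, no factor coercion, `#`-prefixed
#' provenance lines skipped.
#'
#' @param path Path to a TSV file.
#' @param required Character vector of column names that must be present.
#' @return A `data.frame`.
#' @keywords internal
readTsv <- function(path, required = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a tab-delimited table with a provenance header
#'
#' Tables written by the pipeline carry `#`-prefixed header lines recording the
#' package version and, when available, a configuration hash, so an output file
#' identifies the code and settings that produced it. Headers contain no
#' timestamps: repeated runs under identical inputs are byte-identical.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param provenance Optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @keywords internal
writeTsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# glycoCSC %s", as.character(utils::packageVersion("glycoCSC"))), con)
  if (length(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## md5 of the canonical serialization of an R object (used for config hashes).
objectHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

## Parse a boolean-ish TSV cell ("true"/"false"/"TRUE"/"1"/"0"/"yes"/"no").
parseBool <- function(x, what = "boolean") {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(lx) & lx != "" & lx != "na" & is.na(out)
  if (any(bad)) {
    stop("unparseable ", what, " value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}
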