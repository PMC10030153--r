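#' Strip isoform suffixes from accessions
#'
#' UniProt isoforms (`P12345-2`) collapse to the canonical accession by
#' default so presence/absence comparisons across datasets share one
#' namespace.
#'
#' @param accessions Character vector.
#' @param strip Apply the stripping (default `TRUE`).
#' @return Character vector.
#' @export
normalizeAccessions <- function(accessions, strip = TRUE) {
  if (!strip) return(accessions)
  sub("-\\d+$", "", accessions)
}

#' Build a presence/absence matrix across datasets
#'
#' A protein is marked present in a dataset (cell type, region or external
#' catalog) when it was identified in at least `minExperiments` experiments
#' of that dataset. The default of 1 pools all experiments of a dataset.
#'
#' @param identifications `data.frame` with columns `accession`, `dataset`,
#'   `experiment`; one row per identification event (rows for the same
#'   accession within one experiment are collapsed).
#' @param minExperiments Minimum experiment count for presence (default 1).
#' @param datasets Optional character vector of dataset names to force into
#'   the matrix (a dataset with no identifications yields an all-false
#'   column).
#' @param stripIsoforms Collapse isoform accessions, see
#'   [normalizeAccessions()].
#' @return Logical matrix, rows = accessions (sorted), columns = datasets,
#'   with an `experiments` attribute giving the experiment count per dataset.
#' @export
buildPresence <- function(identifications, minExperiments = 1L,
                          datasets = NULL, stripIsoforms = TRUE) {
  need <- c("accession", "dataset", "experiment")
  if (!all(need %in% colnames(identifications))) {
    stop("identifications needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- identifications
  df$accession <- normalizeAccessions(df$accession, strip = stripIsoforms)
  expKey <- unique(df[, c("dataset", "experiment")])
  if (anyDuplicated(expKey$experiment)) {
    dup <- expKey$experiment[duplicated(expKey$experiment)]
    stop("experiment id(s) used in more than one dataset: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df <- unique(df[, need])
  acc <- sort(unique(df$accession))
  datasets <- sort(union(unique(identifications$dataset), datasets))
  m <- matrix(FALSE, nrow = length(acc), ncol = length(datasets),
              dimnames = list(acc, datasets))
  cnt <- table(factor(df$accession, acc), factor(df$dataset, datasets))
  m[] <- cnt >= minExperiments
  attr(m, "experiments") <- vapply(datasets, function(d)
    length(unique(df$experiment[df$dataset == d])), integer(1))
  m
}

#' Exclusive set intersections (UpSet semantics)
#'
#' Assigns every accession to exactly the combination of datasets that
#' contain it, so the exclusive counts partition the accession universe and
#' sum to the number of distinct accessions.
#'
#' @param presence Logical matrix from [buildPresence()] (>= 2 columns).
#' @return `data.frame` sorted by decreasing count: `combination`
#'   (`&`-joined dataset names), `degree`, `count`, and a list-column
#'   `accessions`.
#' @export
exclusiveIntersections <- function(presence) {
  if (ncol(presence) < 2L) stop("need >= 2 datasets", call. = FALSE)
  inAny <- rowSums(presence) > 0L
  presence <- presence[inAny, , drop = FALSE]
  combo <- apply(presence, 1L, function(r)
    paste(colnames(presence)[r], collapse = "&"))
  groups <- split(rownames(presence), combo)
  out <- data.frame(combination = names(groups),
                    degree = lengths(strsplit(names(groups), "&",
                                              fixed = TRUE)),
                    count = lengths(groups), stringsAsFactors = FALSE)
  out$accessions <- lapply(groups, sort)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-catalog comparison (Venn counts)
#'
#' @param a,b Character vectors of accessions.
#' @param stripIsoforms Collapse isoform accessions first.
#' @return List with sorted vectors `a_only`, `shared`, `b_only` and an
#'   integer `counts` vector.
#' @export
compareCatalog <- function(a, b, stripIsoforms = TRUE) {
  a <- unique(normalizeAccessions(a, stripIsoforms))
  b <- unique(normalizeAccessions(b, stripIsoforms))
  res <- list(a_only = sort(setdiff(a, b)),
              shared = sort(intersect(a, b)),
              b_only = sort(setdiff(b, a)))
  res$counts <- c(a_only = length(res$a_only), shared = length(res$shared),
                  b_only = length(res$b_only))
  res
}
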