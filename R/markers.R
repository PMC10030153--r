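#' Gini coefficient of an abundance profile
#'
#' Population form of the Gini dispersion statistic,
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}: 0 for a uniform
#' profile, \eqn{(n-1)/n} for a one-hot profile, invariant to positive
#' rescaling. High Gini means abundance concentrated in few groups -- the
#' dispersion component of marker scoring.
#'
#' @param values Non-negative finite numeric vector, length >= 2, not all
#'   zero.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' giniCoefficient(c(5, 5, 5, 5))   # 0
#' giniCoefficient(c(1, 0, 0, 0))   # 0.75
#' @export
giniCoefficient <- function(values) {
  if (length(values) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  if (all(values == 0)) stop("all-zero profile: Gini undefined", call. = FALSE)
  n <- length(values)
  ## O(n log n) equivalent of the pairwise double sum
  s <- sort(values)
  sum((2 * seq_len(n) - n - 1) * s) / (n^2 * mean(values))
}

#' Scaled signal strength of an abundance profile
#'
#' Log-compressed, capped maximum abundance:
#' `min(log2(1 + max(values)), capLog2) / capLog2`, mapping raw intensity
#' scales (which span many orders of magnitude in MS data) into `[0, 1]`.
#' The default cap of 30 log2 units saturates around raw intensities of 1e9,
#' the upper end of typical Orbitrap precursor areas.
#'
#' @param values Non-negative numeric vector.
#' @param capLog2 Saturation point in log2 units (default 30).
#' @return Scalar in `[0, 1]`.
#' @export
signalStrength <- function(values, capLog2 = 30) {
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  min(log2(1 + max(values)), capLog2) / capLog2
}

#' Score and rank surface-marker candidates
#'
#' Combines three `[0, 1]` components per protein: surface-prediction
#' consensus (SPC/4), Gini dispersion across groups, and scaled signal
#' strength. The full score is the product of all three; the `omni` variant
#' drops the SPC component so candidates without prior surface annotation
#' are not penalized. Ranking is descending by the selected score, with ties
#' broken by accession.
#'
#' @param profiles Numeric matrix, rows = proteins (rownames = accessions),
#'   columns = groups (cell types or regions); non-negative.
#' @param spc Integer vector (0-4) aligned with rows, or named; missing
#'   proteins default to 0.
#' @param mode `"genie"` (SPC x Gini x signal) or `"omni"` (Gini x signal).
#' @param capLog2 Passed to [signalStrength()].
#' @return `data.frame` sorted by rank: `accession`, `gini`, `signal`,
#'   `spc_component`, `genie_score`, `omni_score`, `score`.
#' @export
rankMarkers <- function(profiles, spc = NULL, mode = c("genie", "omni"),
                        capLog2 = 30) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  acc <- rownames(profiles)
  if (is.null(acc)) stop("profiles must have accession rownames",
                         call. = FALSE)
  spcVec <- rep(0L, nrow(profiles))
  names(spcVec) <- acc
  if (!is.null(spc)) {
    if (is.null(names(spc))) spcVec[] <- spc else {
      keep <- intersect(names(spc), acc)
      spcVec[keep] <- spc[keep]
    }
  }
  gini <- apply(profiles, 1L, giniCoefficient)
  signal <- apply(profiles, 1L, signalStrength, capLog2 = capLog2)
  spcComp <- spcVec / 4
  out <- data.frame(accession = acc, gini = gini, signal = signal,
                    spc_component = unname(spcComp),
                    genie_score = unname(spcComp) * gini * signal,
                    omni_score = gini * signal, stringsAsFactors = FALSE)
  out$score <- if (mode == "genie") out$genie_score else out$omni_score
  out <- out[order(-out$score, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract group-restricted marker candidates
#'
#' Candidates exclusive to one cell type or region: present in the target
#' group, absent from every other group of the presence matrix, and absent
#' from every external catalog (e.g. surfaceome compendia of other cell
#' types).
#'
#' @param presence Logical matrix, rows = accessions, columns = groups.
#' @param targetGroup Column name of the group of interest.
#' @param catalogs List of character vectors of accessions to exclude.
#' @return Sorted character vector of restricted accessions.
#' @export
restrictedMarkers <- function(presence, targetGroup, catalogs = list()) {
  if (!targetGroup %in% colnames(presence)) {
    stop("target group not in presence matrix: ", targetGroup, call. = FALSE)
  }
  others <- setdiff(colnames(presence), targetGroup)
  keep <- presence[, targetGroup] &
    (if (length(others)) rowSums(presence[, others, drop = FALSE]) == 0L
     else TRUE)
  acc <- rownames(presence)[keep]
  for (cat in catalogs) acc <- setdiff(acc, cat)
  sort(acc)
}
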