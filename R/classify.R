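#' Classify cell-surface N-glycoproteins
#'
#' The decision rule for calling a protein with sequon-deamidation evidence a
#' cell-surface N-glycoprotein: it is surface if its N-gly-CIRFESS score is
#' positive, or if the score is 0 but the surface-prediction consensus (SPC)
#' is 3-4, or if the score is 0 but a signal peptide is predicted. The
#' rationale: a score of 0 means no extracellular sequon peptide is
#' MS-detectable, so a capture experiment should not have seen the protein --
#' unless topology prediction failed (SPC 3-4 restores confidence in surface
#' localization) or the protein is secreted (signal peptide). The reported
#' branch is the first clause that fires, in that order; the verdict does not
#' depend on the order.
#'
#' @param cirfess Integer vector of N-gly-CIRFESS scores.
#' @param spc Integer vector (0-4) of SPC scores.
#' @param signalPeptide Logical vector of signal-peptide calls.
#' @return `data.frame` with `is_surface` and `branch`
#'   (`cirfess_positive`, `spc_consensus`, `signal_peptide`, `none`).
#' @examples
#' classifySurface(cirfess = c(2, 0, 0, 0), spc = c(0, 3, 2, 0),
#'                 signalPeptide = c(FALSE, FALSE, FALSE, TRUE))
#' @export
classifySurface <- function(cirfess, spc, signalPeptide) {
  n <- length(cirfess)
  stopifnot(length(spc) == n, length(signalPeptide) == n)
  if (any(is.na(cirfess)) || any(cirfess < 0)) {
    stop("cirfess scores must be non-negative", call. = FALSE)
  }
  if (any(!spc %in% 0:4)) stop("spc must be in 0..4", call. = FALSE)
  branch <- rep("none", n)
  branch[cirfess == 0 & signalPeptide] <- "signal_peptide"
  branch[cirfess == 0 & spc %in% c(3L, 4L)] <- "spc_consensus"
  branch[cirfess > 0] <- "cirfess_positive"
  data.frame(is_surface = branch != "none", branch = branch,
             stringsAsFactors = FALSE)
}

#' Infer transmembrane orientation from glycosite parity
#'
#' N-glycosylation happens in the ER lumen, so an observed glycosite pins its
#' inter-membrane loop to the extracellular side. Membrane passes alternate
#' sides, so one pinned loop propagates an orientation to the N-terminus:
#' loops are numbered 0 (N-terminal side), 1, ... between successive
#' transmembrane segments; a glycosite in an even-numbered loop implies the
#' N-terminus is extracellular (N-out), an odd-numbered loop implies N-in.
#' Glycosites on both parities are topologically impossible and yield
#' `conflict`; none yield `undetermined`. Sites falling inside a
#' transmembrane segment are flagged and excluded from the parity vote.
#'
#' @param glycositePositions Integer vector of protein positions of observed
#'   glycosites (order and duplicates are irrelevant).
#' @param tmSegments `data.frame` with `start`, `end` of transmembrane
#'   segments (>= 1 required).
#' @param databaseOrientation Optional `"N-out"`/`"N-in"` annotation to
#'   compare against.
#' @return List: `orientation` (`"N-out"`, `"N-in"`, `"undetermined"`),
#'   `status` (`"consistent"`, `"conflict"`, `"undetermined"`),
#'   `conflicting` (logical: both parities implicated),
#'   `excluded_sites` (positions inside transmembrane segments).
#' @export
inferOrientation <- function(glycositePositions, tmSegments,
                             databaseOrientation = NA_character_) {
  if (is.null(tmSegments) || !nrow(tmSegments)) {
    stop("orientation inference requires at least one transmembrane segment",
         call. = FALSE)
  }
  tm <- tmSegments[order(tmSegments$start), , drop = FALSE]
  pos <- sort(unique(as.integer(glycositePositions)))
  inTm <- vapply(pos, function(p) any(p >= tm$start & p <= tm$end),
                 logical(1))
  excluded <- pos[inTm]
  pos <- pos[!inTm]
  ## loop index of a position = number of TM segments entirely before it
  loop <- vapply(pos, function(p) sum(tm$end < p), integer(1))
  parity <- unique(loop %% 2L)
  conflicting <- length(parity) > 1L
  orientation <- if (!length(parity)) "undetermined"
    else if (conflicting) "undetermined"
    else if (parity == 0L) "N-out" else "N-in"
  status <- if (conflicting) "conflict"
    else if (orientation == "undetermined") "undetermined"
    else if (is.na(databaseOrientation)) "undetermined"
    else if (identical(orientation, databaseOrientation)) "consistent"
    else "conflict"
  list(orientation = orientation, status = status,
       conflicting = conflicting, excluded_sites = excluded)
}

#' Curate PSM evidence into a classified surface catalog
#'
#' End-to-end curation: maps deamidation-in-sequon evidence to protein
#' coordinates, resolves master proteins, computes capture specificity,
#' scores in-silico detectability, and classifies each master protein with
#' sequon evidence as surface or not. The result holds the full evidence
#' table (all master proteins with >= 1 sequon-deamidated peptide) and the
#' filtered subset passing the surface classifier.
#'
#' @param psms Table from [readPsmTable()].
#' @param proteins `AAStringSet` database.
#' @param topology Topology table from [readTopology()], or `NULL`.
#' @param surfacePred Surface-prediction table from
#'   [readSurfacePredictions()], or `NULL` (worst case assumed).
#' @param cirfess Optional precomputed [CirfessResult-class]; computed from
#'   `topology`/`surfacePred` when missing.
#' @param includeNxc,missedCleavages,spRule Passed to the scoring and
#'   flagging steps.
#' @param collapseIL Passed to [assignMasterProteins()].
#' @return A [SurfaceCatalog-class] object.
#' @export
curateCatalog <- function(psms, proteins, topology = NULL,
                          surfacePred = NULL, cirfess = NULL,
                          includeNxc = FALSE, missedCleavages = 0L,
                          spRule = c("any", "majority"), collapseIL = FALSE) {
  spRule <- match.arg(spRule)
  evidence <- flagScmDeamidation(psms, proteins, includeNxc = includeNxc)
  assignment <- assignMasterProteins(psms, proteins, collapseIL = collapseIL)
  specificity <- computeSpecificity(psms, evidence, assignment)
  if (is.null(cirfess)) {
    cirfess <- cirfessScore(proteins, topology = topology,
                            surfacePred = surfacePred,
                            missedCleavages = missedCleavages,
                            includeNxc = includeNxc, spRule = spRule)
  }
  cs <- cirfessScores(cirfess)

  spFlag <- rep(FALSE, length(proteins))
  names(spFlag) <- names(proteins)
  spcScore <- rep(0L, length(proteins))
  names(spcScore) <- names(proteins)
  if (!is.null(surfacePred)) {
    spFlag[surfacePred$accession] <- signalPeptideCall(surfacePred,
                                                       rule = spRule)
    spcScore[surfacePred$accession] <- surfacePred$spc_score
  }

  ## master proteins with >= 1 sequon-deamidated peptide form the SCM table;
  ## evidence on a grouped accession counts for its master.
  masters <- assignment$masters
  groupLookup <- c(setNames(masters$accession, masters$accession))
  for (i in seq_len(nrow(masters))) {
    gm <- strsplit(masters$grouped_accessions[i], ";", fixed = TRUE)[[1L]]
    gm <- gm[nzchar(gm)]
    if (length(gm)) groupLookup[gm] <- masters$accession[i]
  }
  evMaster <- unname(groupLookup[evidence$accession])
  scmMasters <- sort(unique(evMaster[!is.na(evMaster)]))

  ## aggregate site-level evidence per (master, position)
  keep <- !is.na(evMaster)
  glyco <- if (any(keep)) {
    ev <- evidence[keep, , drop = FALSE]
    ev$accession <- evMaster[keep]
    agg <- split(ev, paste(ev$accession, ev$position, sep = "\r"))
    out <- do.call(rbind, lapply(agg, function(g) data.frame(
      accession = g$accession[1L], position = g$position[1L],
      motif = g$motif[1L], motif_class = g$motif_class[1L],
      n_psms = length(unique(g$spectrum_id)),
      psm_ids = paste(sort(unique(g$spectrum_id)), collapse = ";"),
      ambiguous = any(g$ambiguous), stringsAsFactors = FALSE)))
    out <- out[order(out$accession, out$position), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(accession = character(), position = integer(),
               motif = character(), motif_class = character(),
               n_psms = integer(), psm_ids = character(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  }

  psmScm <- psms$spectrum_id %in% unique(evidence$spectrum_id)
  summaries <- do.call(rbind, lapply(scmMasters, function(m) {
    mine <- vapply(assignment$psmMasters, function(x) m %in% x, logical(1))
    data.frame(accession = m,
               n_psms_total = sum(mine),
               n_psms_scm = sum(mine & psmScm),
               n_unique_peptides =
                 masters$n_unique_peptides[masters$accession == m],
               n_glycosites = sum(glyco$accession == m),
               cirfess_score = cs$score[match(m, cs$accession)],
               spc_score = unname(spcScore[m]),
               signal_peptide = unname(spFlag[m]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summaries)) {
    summaries <- data.frame(accession = character(), n_psms_total = integer(),
                            n_psms_scm = integer(),
                            n_unique_peptides = integer(),
                            n_glycosites = integer(),
                            cirfess_score = integer(), spc_score = integer(),
                            signal_peptide = logical(),
                            stringsAsFactors = FALSE)
  }
  rownames(summaries) <- NULL
  cls <- if (nrow(summaries)) {
    cbind(data.frame(accession = summaries$accession,
                     stringsAsFactors = FALSE),
          classifySurface(summaries$cirfess_score, summaries$spc_score,
                          summaries$signal_peptide))
  } else {
    data.frame(accession = character(), is_surface = logical(),
               branch = character(), stringsAsFactors = FALSE)
  }
  new("SurfaceCatalog", summaries = summaries, classification = cls,
      glycosites = glyco, specificity = specificity)
}
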