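## Logical mask of extracellular residues for one protein, combining topology
## regions from all predictors by union, with the signal-peptide fallback:
## a protein with a signal peptide and no transmembrane segment exposes its
## whole mature chain. Returns list(mask = logical(len), source = character).
extracellularMask <- function(len, topo, hasSignalPeptide) {
  mask <- rep(FALSE, len)
  source <- "none"
  if (!is.null(topo) && nrow(topo)) {
    ext <- topo[topo$label == "extracellular", , drop = FALSE]
    for (i in seq_len(nrow(ext))) mask[ext$start[i]:ext$end[i]] <- TRUE
    if (nrow(ext)) source <- "topology"
    hasTm <- any(topo$label == "transmembrane")
    spRegions <- topo[topo$label == "signal_peptide", , drop = FALSE]
    if (nrow(spRegions)) hasSignalPeptide <- TRUE
    if (hasSignalPeptide && !hasTm) {
      matureFrom <- if (nrow(spRegions)) max(spRegions$end) + 1L else 1L
      if (matureFrom <= len) mask[matureFrom:len] <- TRUE
      source <- if (source == "none") "signal_peptide" else source
    }
  } else if (hasSignalPeptide) {
    mask[] <- TRUE
    source <- "signal_peptide"
  }
  list(mask = mask, source = source)
}

#' Score in-silico detectability of extracellular sequon peptides
#'
#' Computes the N-gly-CIRFESS score for each protein: the number of distinct
#' tryptic peptides that (a) carry at least one N-glycosylation sequon whose
#' asparagine lies in a region called extracellular by at least one topology
#' predictor, and (b) pass the MS detectability filter (length >= 6 and
#' 2+/3+ m/z below 2,000). A score of 0 means no predicted extracellular
#' sequon peptide is suitable for MS analysis, so the protein would not be
#' specifically captured by a cell-surface capture experiment. Proteins with
#' a signal peptide and no transmembrane segment are treated as secreted or
#' anchored with the whole mature chain extracellular.
#'
#' Topology calls from multiple predictors are combined by union: a residue
#' counted extracellular by any one predictor qualifies. Predictors disagree
#' on real proteins (transmembrane-helix false-classification rates of a few
#' percent are typical), and requiring consensus would discard genuine
#' surface proteins.
#'
#' @param proteins `AAStringSet` from [readProteome()].
#' @param topology Topology `data.frame` from [readTopology()], or `NULL`.
#' @param surfacePred Table from [readSurfacePredictions()], or `NULL`; used
#'   only for its signal-peptide calls.
#' @param missedCleavages Missed cleavages allowed in the digest (default 0).
#' @param includeNxc Also count N-X-C sequons (default `FALSE`).
#' @param spRule Signal-peptide voting rule, see [signalPeptideCall()].
#' @return A [CirfessResult-class] object.
#' @export
cirfessScore <- function(proteins, topology = NULL, surfacePred = NULL,
                         missedCleavages = 0L, includeNxc = FALSE,
                         spRule = c("any", "majority")) {
  spRule <- match.arg(spRule)
  spFlag <- rep(FALSE, length(proteins))
  names(spFlag) <- names(proteins)
  if (!is.null(surfacePred)) {
    got <- signalPeptideCall(surfacePred, rule = spRule)
    spFlag[names(got)] <- got
  }
  topoByAcc <- if (!is.null(topology) && nrow(topology)) {
    split(topology, topology$accession)
  } else list()

  scores <- data.frame(accession = names(proteins), score = 0L,
                       topology_source = "none", stringsAsFactors = FALSE)
  pepRows <- list()
  for (i in seq_along(proteins)) {
    acc <- names(proteins)[i]
    seqStr <- as.character(proteins[[i]])
    len <- nchar(seqStr)
    em <- extracellularMask(len, topoByAcc[[acc]], spFlag[[acc]])
    scores$topology_source[i] <- em$source
    if (!any(em$mask)) next
    sites <- findScmSites(seqStr, includeNxc = includeNxc)
    if (!nrow(sites)) next
    sites <- sites[em$mask[sites$position], , drop = FALSE]
    if (!nrow(sites)) next
    peps <- digestProtein(seqStr, missedCleavages = missedCleavages)
    hit <- vapply(seq_len(nrow(peps)), function(j) {
      any(sites$position >= peps$start[j] & sites$position <= peps$end[j])
    }, logical(1))
    peps <- peps[hit, , drop = FALSE]
    if (!nrow(peps)) next
    det <- assessDetectability(peps$sequence)
    peps <- cbind(peps, det[, c("monoisotopic_mass", "mz2", "mz3",
                                "detectable")])
    peps <- peps[peps$detectable, , drop = FALSE]
    if (!nrow(peps)) next
    ## expand to (peptide, sequon) pairs for the contributing-peptide table
    pairs <- do.call(rbind, lapply(seq_len(nrow(peps)), function(j) {
      s <- sites[sites$position >= peps$start[j] &
                   sites$position <= peps$end[j], , drop = FALSE]
      data.frame(accession = acc,
                 start = peps$start[j], end = peps$end[j],
                 sequence = peps$sequence[j],
                 missed_cleavages = peps$missed_cleavages[j],
                 scm_position = s$position, motif = s$motif,
                 motif_class = s$motif_class,
                 monoisotopic_mass = peps$monoisotopic_mass[j],
                 mz2 = peps$mz2[j], mz3 = peps$mz3[j],
                 stringsAsFactors = FALSE)
    }))
    pepRows[[acc]] <- pairs
    scores$score[i] <- length(unique(paste(peps$start, peps$end)))
  }
  peptides <- if (length(pepRows)) do.call(rbind, pepRows) else
    data.frame(accession = character(), start = integer(), end = integer(),
               sequence = character(), missed_cleavages = integer(),
               scm_position = integer(), motif = character(),
               motif_class = character(), monoisotopic_mass = numeric(),
               mz2 = numeric(), mz3 = numeric(), stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  new("CirfessResult", scores = scores, peptides = peptides)
}
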