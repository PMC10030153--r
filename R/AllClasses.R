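#' @import methods
NULL

#' Per-protein in-silico detectability scores (N-gly-CIRFESS)
#'
#' Container for the N-gly-CIRFESS score of each protein -- the count of
#' distinct tryptic peptides carrying at least one N-glycosylation sequon
#' whose asparagine lies in a predicted extracellular region and that pass
#' the MS detectability filter -- together with the contributing peptides.
#'
#' @slot scores `data.frame` with one row per scored protein: `accession`,
#'   `score` (non-negative integer), `topology_source` (`"topology"`,
#'   `"signal_peptide"` or `"none"`).
#' @slot peptides `data.frame` of contributing (peptide, sequon) pairs:
#'   `accession`, `start`, `end`, `sequence`, `missed_cleavages`,
#'   `scm_position`, `motif`, `motif_class`, `monoisotopic_mass`, `mz2`,
#'   `mz3`.
#'
#' @seealso [cirfessScore()], [cirfessScores()], [contributingPeptides()]
#' @export
setClass("CirfessResult",
         representation(scores = "data.frame", peptides = "data.frame"))

setValidity("CirfessResult", function(object) {
  sc <- object@scores
  pep <- object@peptides
  need <- c("accession", "score", "topology_source")
  if (!all(need %in% colnames(sc))) {
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  }
  if (any(sc$score < 0L)) return("scores must be non-negative")
  ## score = number of distinct contributing peptides; 0 <=> none listed
  key <- paste(pep$accession, pep$start, pep$end, sep = "\r")
  n <- tapply(!duplicated(key), pep$accession, sum)
  got <- integer(nrow(sc))
  got[match(names(n), sc$accession)] <- as.integer(n)
  if (!identical(got, as.integer(sc$score))) {
    return("score must equal the number of distinct contributing peptides")
  }
  TRUE
})

setMethod("show", "CirfessResult", function(object) {
  sc <- object@scores
  cat("CirfessResult:", nrow(sc), "protein(s),",
      sum(sc$score > 0L), "with score > 0;",
      nrow(object@peptides), "contributing peptide-sequon pair(s)\n")
})

#' Curated cell-surface N-glycoprotein catalog
#'
#' Result of the PSM curation workflow: per-protein evidence summaries for
#' all master proteins with at least one deamidated-in-sequon peptide (the
#' SCM table), the subset classified as cell-surface N-glycoproteins (the
#' SCM-filtered table), the site-level glycosite evidence, and the capture
#' specificity report.
#'
#' @slot summaries `data.frame`, one row per master protein with SCM
#'   evidence: PSM and peptide counts, glycosite count, CIRFESS score, SPC
#'   score, signal-peptide flag.
#' @slot classification `data.frame`: `accession`, `is_surface`, `branch`
#'   (`cirfess_positive`, `spc_consensus`, `signal_peptide` or `none`).
#' @slot glycosites `data.frame` of site-level evidence (accession, protein
#'   position of the deamidated N, motif, supporting PSM ids).
#' @slot specificity list with `psm_level` and `protein_level` percentages
#'   and their numerators/denominators.
#'
#' @seealso [curateCatalog()], [scmTable()], [scmFilteredTable()]
#' @export
setClass("SurfaceCatalog",
         representation(summaries = "data.frame",
                        classification = "data.frame",
                        glycosites = "data.frame",
                        specificity = "list"))

setValidity("SurfaceCatalog", function(object) {
  cl <- object@classification
  if (!all(c("accession", "is_surface", "branch") %in% colnames(cl))) {
    return("classification must have accession, is_surface, branch")
  }
  if (!all(cl$is_surface == (cl$branch != "none"))) {
    return("is_surface must hold exactly when a decision branch fired")
  }
  if (!all(cl$accession %in% object@summaries$accession)) {
    return("classified accessions must be a subset of summarized ones")
  }
  sp <- object@specificity
  for (lev in c("psm_level", "protein_level")) {
    if (!is.null(sp[[lev]]) && !is.na(sp[[lev]]$percent)) {
      if (sp[[lev]]$percent < 0 || sp[[lev]]$percent > 100) {
        return("specificity percentages must lie in [0, 100]")
      }
    }
  }
  TRUE
})

setMethod("show", "SurfaceCatalog", function(object) {
  cat("SurfaceCatalog:", nrow(object@summaries),
      "master protein(s) with SCM evidence;",
      sum(object@classification$is_surface),
      "classified cell-surface N-glycoprotein(s)\n")
  sp <- object@specificity
  if (!is.null(sp$psm_level)) {
    cat(sprintf("  capture specificity: %.1f%% (PSM), %.1f%% (protein)\n",
                sp$psm_level$percent, sp$protein_level$percent))
  }
})

#' @rdname CirfessResult-class
#' @param object A `CirfessResult`.
#' @return `cirfessScores()`: the per-protein score table.
#' @export
setGeneric("cirfessScores", function(object) standardGeneric("cirfessScores"))

#' @rdname CirfessResult-class
#' @export
setMethod("cirfessScores", "CirfessResult", function(object) object@scores)

#' @rdname CirfessResult-class
#' @return `contributingPeptides()`: the peptide-sequon pair table.
#' @export
setGeneric("contributingPeptides",
           function(object) standardGeneric("contributingPeptides"))

#' @rdname CirfessResult-class
#' @export
setMethod("contributingPeptides", "CirfessResult",
          function(object) object@peptides)

#' @rdname SurfaceCatalog-class
#' @param object A `SurfaceCatalog`.
#' @return `scmTable()`: summaries of all master proteins with SCM evidence.
#' @export
setGeneric("scmTable", function(object) standardGeneric("scmTable"))

#' @rdname SurfaceCatalog-class
#' @export
setMethod("scmTable", "SurfaceCatalog", function(object) {
  merge(object@summaries, object@classification, by = "accession",
        sort = TRUE)
})

#' @rdname SurfaceCatalog-class
#' @return `scmFilteredTable()`: the subset classified as cell surface.
#' @export
setGeneric("scmFilteredTable",
           function(object) standardGeneric("scmFilteredTable"))

#' @rdname SurfaceCatalog-class
#' @export
setMethod("scmFilteredTable", "SurfaceCatalog", function(object) {
  t <- scmTable(object)
  out <- t[t$is_surface, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @rdname SurfaceCatalog-class
#' @return `glycositeTable()`: site-level glycosite evidence.
#' @export
setGeneric("glycositeTable", function(object) standardGeneric("glycositeTable"))

#' @rdname SurfaceCatalog-class
#' @export
setMethod("glycositeTable", "SurfaceCatalog", function(object) object@glycosites)

#' @rdname SurfaceCatalog-class
#' @return `captureSpecificity()`: the specificity report list.
#' @export
setGeneric("captureSpecificity",
           function(object) standardGeneric("captureSpecificity"))

#' @rdname SurfaceCatalog-class
#' @export
setMethod("captureSpecificity", "SurfaceCatalog",
          function(object) object@specificity)
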