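.DEAMIDATION_DELTA <- 0.98402

## Parse one generic-dialect modification cell: entries "pos|name[|delta]"
## joined by ";". Returns data.frame(position, name, delta) or NULL on error.
.parseModsGeneric <- function(cell, pepLen) {
  if (is.na(cell) || !nzchar(trimws(cell))) {
    return(data.frame(position = integer(), name = character(),
                      delta = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(cell), ";", fixed = TRUE)[[1L]]
  rows <- lapply(parts, function(p) {
    f <- strsplit(trimws(p), "|", fixed = TRUE)[[1L]]
    if (length(f) < 2L) return(NULL)
    pos <- suppressWarnings(as.integer(f[1L]))
    delta <- if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else
      unname(.MOD_DELTAS[f[2L]])
    if (is.na(pos) || pos < 1L || pos > pepLen) return(NULL)
    data.frame(position = pos, name = f[2L],
               delta = ifelse(is.na(delta), NA_real_, delta),
               stringsAsFactors = FALSE)
  })
  if (any(vapply(rows, is.null, logical(1)))) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## Parse one ProteomeDiscoverer-style modification cell, e.g.
## "1xDeamidated [N4]; 2xCarbamidomethyl [C2; C10]".
.parseModsPd <- function(cell, pepLen) {
  if (is.na(cell) || !nzchar(trimws(cell))) {
    return(data.frame(position = integer(), name = character(),
                      delta = numeric(), stringsAsFactors = FALSE))
  }
  ## split on "; " only between groups (a group ends with "]")
  groups <- regmatches(cell,
                       gregexpr("\\d+x[A-Za-z0-9_-]+ \\[[^]]*\\]", cell))[[1L]]
  if (!length(groups)) return(NULL)
  rows <- lapply(groups, function(g) {
    m <- regmatches(g, regexec("^(\\d+)x([A-Za-z0-9_-]+) \\[([^]]*)\\]$", g))[[1L]]
    if (length(m) != 4L) return(NULL)
    name <- m[3L]
    sites <- strsplit(m[4L], ";", fixed = TRUE)[[1L]]
    pos <- suppressWarnings(as.integer(sub("^\\s*[A-Z]", "", trimws(sites))))
    if (anyNA(pos) || any(pos < 1L | pos > pepLen)) return(NULL)
    if (length(pos) != as.integer(m[2L])) return(NULL)
    data.frame(position = pos, name = name,
               delta = unname(.MOD_DELTAS[name])[1L],
               stringsAsFactors = FALSE)
  })
  if (any(vapply(rows, is.null, logical(1)))) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a PSM-level search-engine export
#'
#' Parses a peptide-spectrum-match table into one record per row with the
#' modification strings resolved to (position-in-peptide, name, delta-Da)
#' triples. Two dialects are supported: `"generic"` (modification cells are
#' `position|name[|delta]` entries joined by `;`) and `"pd"`
#' (ProteomeDiscoverer-style cells such as `1xDeamidated [N4]`). Rows whose
#' modification cell cannot be parsed are dropped with a warning reporting
#' the count.
#'
#' @param path TSV with columns `spectrum_id`, `peptide`, `modifications`,
#'   `proteins` (accessions joined by `;`), and optional `intensity`, `run`.
#' @param dialect `"generic"` or `"pd"`.
#' @return `data.frame` with list-columns `modifications` (data.frames) and
#'   `proteins` (character vectors).
#' @export
readPsmTable <- function(path, dialect = c("generic", "pd")) {
  dialect <- match.arg(dialect)
  df <- readTsv(path, required = c("spectrum_id", "peptide", "modifications",
                                   "proteins"))
  df$peptide <- toupper(trimws(df$peptide))
  parser <- if (dialect == "pd") .parseModsPd else .parseModsGeneric
  mods <- Map(parser, df$modifications, nchar(df$peptide))
  bad <- vapply(mods, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " PSM row(s) dropped: unparseable modification string",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    mods <- mods[!bad]
  }
  out <- data.frame(spectrum_id = as.character(df$spectrum_id),
                    peptide = df$peptide, stringsAsFactors = FALSE)
  out$modifications <- unname(mods)
  out$proteins <- lapply(strsplit(df$proteins, ";", fixed = TRUE), trimws)
  out$intensity <- if ("intensity" %in% colnames(df))
    as.numeric(df$intensity) else NA_real_
  out$run <- if ("run" %in% colnames(df)) as.character(df$run) else
    NA_character_
  rownames(out) <- NULL
  out
}

## Deamidated-N modifications of one PSM: by name ("Deamidated", any case)
## or by delta within +/- 0.01 Da of the deamidation mass shift, on an N.
.deamidatedPositions <- function(mods, peptide) {
  if (is.null(mods) || !nrow(mods)) return(integer())
  byName <- grepl("deamid", mods$name, ignore.case = TRUE)
  byDelta <- !is.na(mods$delta) &
    abs(mods$delta - .DEAMIDATION_DELTA) <= 0.01
  pos <- mods$position[byName | byDelta]
  pos[substring(peptide, pos, pos) == "N"]
}

#' Map deamidation-in-sequon evidence to protein coordinates
#'
#' For every deamidated asparagine of every PSM, locates the peptide in each
#' listed protein and tests the N-glycosylation sequon in protein context --
#' the two residues after the N are taken from the protein, so a motif whose
#' window extends past the peptide's C-terminus is still recognized. Evidence
#' is emitted only where the sequon holds. Glycans attach to the sequon N;
#' deamidation (N to D, +0.98402 Da) is the mass mark left by enzymatic
#' deglycosylation, so a deamidated N inside a sequon is the signature of a
#' formerly glycosylated site.
#'
#' @param psms Table from [readPsmTable()].
#' @param proteins `AAStringSet` from [readProteome()].
#' @param includeNxc Accept N-X-C sequons too (default `FALSE`).
#' @return `data.frame` with one row per (PSM, protein, site):
#'   `spectrum_id`, `accession`, `position` (protein coordinate of the N),
#'   `motif`, `motif_class`, `peptide`, `ambiguous` (peptide maps to more
#'   than one position in that protein).
#' @export
flagScmDeamidation <- function(psms, proteins, includeNxc = FALSE) {
  seqs <- as.character(proteins)
  rows <- list()
  for (i in seq_len(nrow(psms))) {
    pep <- psms$peptide[i]
    dpos <- .deamidatedPositions(psms$modifications[[i]], pep)
    accs <- intersect(psms$proteins[[i]], names(proteins))
    if (!length(accs)) {
      stop("PSM ", psms$spectrum_id[i],
           ": no listed protein present in the database", call. = FALSE)
    }
    found <- FALSE
    for (acc in accs) {
      occ <- gregexpr(pep, seqs[[acc]], fixed = TRUE)[[1L]]
      if (occ[1L] == -1L) next
      found <- TRUE
      if (!length(dpos)) next
      ambiguous <- length(occ) > 1L
      for (o in as.integer(occ)) {
        for (p in dpos) {
          protPos <- o + p - 1L
          win <- substring(seqs[[acc]], protPos, protPos + 2L)
          hit <- findScmSites(win, includeNxc = includeNxc)
          if (nrow(hit) && hit$position[1L] == 1L) {
            rows[[length(rows) + 1L]] <- data.frame(
              spectrum_id = psms$spectrum_id[i], accession = acc,
              position = protPos, motif = hit$motif[1L],
              motif_class = hit$motif_class[1L], peptide = pep,
              ambiguous = ambiguous, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (!found) {
      stop("PSM ", psms$spectrum_id[i], ": peptide ", pep,
           " not found in any listed protein", call. = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(spectrum_id = character(), accession = character(),
                      position = integer(), motif = character(),
                      motif_class = character(), peptide = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve master proteins by peptide uniqueness
#'
#' Groups database proteins by the observed peptides they can explain.
#' Proteins with identical observed-peptide sets collapse to one group whose
#' representative is the lexicographically smallest accession. A group
#' identified by at least one peptide unique to it (contained in no other
#' group's proteins) is a master; groups supported only by shared peptides
#' are folded into the master sharing the most peptides (ties broken
#' lexicographically) and excluded from unique counts. Peptide-to-protein
#' mapping is by subsequence search of the whole database; isoleucine and
#' leucine are distinct unless `collapseIL`.
#'
#' @param psms Table from [readPsmTable()].
#' @param proteins `AAStringSet` database.
#' @param collapseIL Treat I and L as equivalent for matching (default
#'   `FALSE`).
#' @return A list: `masters` -- `data.frame` with `accession`,
#'   `n_unique_peptides`, `n_peptides`, `grouped_accessions` (`;`-joined);
#'   `psmAssignment` -- character vector, the master accession each PSM row
#'   is counted under (`NA` where the peptide matches no master uniquely
#'   follows the shared-peptide rule below).
#' @export
assignMasterProteins <- function(psms, proteins, collapseIL = FALSE) {
  if (!nrow(psms)) stop("empty PSM table", call. = FALSE)
  xf <- if (collapseIL) function(s) chartr("I", "L", s) else identity
  seqs <- xf(as.character(proteins))
  peptides <- unique(xf(psms$peptide))
  ## peptide -> accessions containing it (whole-database search)
  pepMap <- lapply(peptides, function(p) {
    names(seqs)[vapply(seqs, function(s) grepl(p, s, fixed = TRUE),
                       logical(1))]
  })
  names(pepMap) <- peptides
  if (any(lengths(pepMap) == 0L)) {
    stop("peptide(s) not found in the database: ",
         paste(peptides[lengths(pepMap) == 0L], collapse = ", "),
         call. = FALSE)
  }
  ## protein -> observed peptide set
  protPeps <- split(rep(peptides, lengths(pepMap)), unlist(pepMap))
  protPeps <- lapply(protPeps, sort)
  ## collapse identical peptide sets; representative = smallest accession
  setKey <- vapply(protPeps, paste, character(1), collapse = "\r")
  groups <- split(names(protPeps), setKey)
  rep_ <- vapply(groups, function(g) sort(g)[1L], character(1))
  groupOf <- setNames(rep(rep_, lengths(groups)), unlist(groups))
  groupPeps <- protPeps[rep_]
  names(groupPeps) <- rep_
  ## uniqueness at group level
  pepGroups <- lapply(pepMap, function(a) unique(unname(groupOf[a])))
  uniqueTo <- vapply(pepGroups, function(g)
    if (length(g) == 1L) g else NA_character_, character(1))
  nUnique <- vapply(names(groupPeps), function(g)
    sum(uniqueTo[groupPeps[[g]]] == g, na.rm = TRUE), integer(1))
  masters <- names(groupPeps)[nUnique > 0L]
  ## fold shared-only groups into the master sharing most peptides
  fold <- setNames(names(groupPeps), names(groupPeps))
  for (g in setdiff(names(groupPeps), masters)) {
    shared <- vapply(masters, function(m)
      length(intersect(groupPeps[[g]], groupPeps[[m]])), integer(1))
    if (length(masters) && max(shared) > 0L) {
      best <- masters[shared == max(shared)]
      fold[[g]] <- sort(best)[1L]
    } else {
      masters <- sort(c(masters, g))  # orphan group: stands as its own master
    }
  }
  memberOf <- setNames(unname(fold[groupOf]), names(groupOf))
  grouped <- vapply(masters, function(m)
    paste(sort(setdiff(names(memberOf)[memberOf == m], m)), collapse = ";"),
    character(1))
  out <- data.frame(accession = masters,
                    n_unique_peptides = as.integer(nUnique[masters]),
                    n_peptides = lengths(groupPeps[masters]),
                    grouped_accessions = grouped,
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  ## assign each PSM to the master group(s) able to explain its peptide;
  ## a peptide shared between masters counts once under each.
  psmMasters <- lapply(xf(psms$peptide), function(p)
    sort(unique(unname(fold[pepGroups[[p]]]))))
  list(masters = out, psmMasters = psmMasters)
}

#' Capture specificity of a cell-surface enrichment experiment
#'
#' The enrichment-quality metric of glycoprotein capture: the percentage of
#' PSMs (and of master proteins) carrying at least one deamidation within an
#' N-glycosylation sequon, out of all PSMs (master proteins).
#'
#' @param psms Table from [readPsmTable()].
#' @param evidence Site evidence from [flagScmDeamidation()].
#' @param masterAssignment Result of [assignMasterProteins()].
#' @return List with `psm_level` and `protein_level`, each holding `percent`,
#'   `numerator` and `denominator`.
#' @export
computeSpecificity <- function(psms, evidence, masterAssignment) {
  nPsm <- nrow(psms)
  if (nPsm == 0L) stop("no PSMs: specificity undefined", call. = FALSE)
  scmPsm <- unique(evidence$spectrum_id)
  nPsmScm <- sum(psms$spectrum_id %in% scmPsm)
  masters <- masterAssignment$masters$accession
  if (!length(masters)) stop("no master proteins: specificity undefined",
                             call. = FALSE)
  ## a master has SCM evidence when any of its PSMs carries sequon deamidation
  scmFlag <- psms$spectrum_id %in% scmPsm
  mastersScm <- unique(unlist(masterAssignment$psmMasters[scmFlag]))
  nProtScm <- sum(masters %in% mastersScm)
  list(psm_level = list(percent = 100 * nPsmScm / nPsm,
                        numerator = nPsmScm, denominator = nPsm),
       protein_level = list(percent = 100 * nProtScm / length(masters),
                            numerator = nProtScm,
                            denominator = length(masters)))
}
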