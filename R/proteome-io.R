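## Valid residue alphabet: the 20 canonical amino acids plus X (unknown).
.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.TOPOLOGY_LABELS <- c("extracellular", "transmembrane", "cytoplasmic",
                      "signal_peptide")

#' Read a protein sequence database
#'
#' Reads a FASTA protein database into an [Biostrings::AAStringSet]. The
#' accession is the first whitespace-delimited token of each header; the
#' remainder is kept as a `description` metadata column. Sequences are
#' uppercased and restricted to the 20 canonical residues plus `X` (unknown).
#' Protein coordinates throughout the package are 1-based inclusive, the
#' UniProt convention.
#'
#' @param path Path to a FASTA file.
#' @return An `AAStringSet` named by accession, with `mcols()$description`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKNGSAVLLK", ">P2", "acdefgh"), fa)
#' prot <- readProteome(fa)
#' names(prot)
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("not a readable FASTA file: ", path,
                                          " (", conditionMessage(e), ")",
                                          call. = FALSE))
  if (length(aa) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  aa <- Biostrings::AAStringSet(toupper(as.character(aa)))
  if (any(Biostrings::width(aa) == 0L)) {
    stop("empty sequence for accession(s): ",
         paste(acc[Biostrings::width(aa) == 0L], collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", paste(.AA_ALPHABET, collapse = "")),
               as.character(aa))
  if (any(bad)) {
    stop("sequence with residues outside the allowed alphabet (20 canonical ",
         "amino acids + X): ", paste(acc[bad], collapse = ", "), call. = FALSE)
  }
  names(aa) <- acc
  S4Vectors::mcols(aa) <- S4Vectors::DataFrame(description = desc)
  aa
}

#' Write a protein database to FASTA
#'
#' Inverse of [readProteome()]: `readProteome(writeProteome(x, f))` is the
#' identity on accessions, descriptions and sequences.
#'
#' @param proteins An `AAStringSet` as returned by [readProteome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteins, path) {
  out <- proteins
  desc <- S4Vectors::mcols(proteins)$description
  if (!is.null(desc)) {
    nm <- ifelse(nzchar(desc), paste(names(proteins), desc), names(proteins))
    names(out) <- nm
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read per-protein topology annotations
#'
#' Loads membrane-topology regions called by one or more sequence-based
#' predictors (for example Phobius-style or TMHMM-style tools, run outside
#' this package). Each row is one region of one predictor's call for one
#' protein. Regions are validated against the protein lengths; within one
#' predictor's call the regions must be non-overlapping.
#'
#' @param path TSV with columns `accession`, `predictor`, `start`, `end`,
#'   `label`; labels are `extracellular`, `transmembrane`, `cytoplasmic` or
#'   `signal_peptide`; coordinates 1-based inclusive.
#' @param proteins `AAStringSet` the annotations refer to.
#' @param unknownAccession `"error"` (default) rejects rows whose accession is
#'   not in `proteins`; `"drop"` discards them with a message.
#' @return A `data.frame` with the validated columns, sorted by accession,
#'   predictor and start.
#' @export
readTopology <- function(path, proteins,
                         unknownAccession = c("error", "drop")) {
  unknownAccession <- match.arg(unknownAccession)
  df <- readTsv(path, required = c("accession", "predictor", "start", "end",
                                   "label"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validateTopology(df, proteins, unknownAccession)
}

## Shared validator so programmatically built topology tables obey the same
## contract as loaded ones.
validateTopology <- function(df, proteins,
                             unknownAccession = c("error", "drop")) {
  unknownAccession <- match.arg(unknownAccession)
  bad <- setdiff(unique(df$accession), names(proteins))
  if (length(bad)) {
    if (unknownAccession == "error") {
      stop("topology references unknown accession(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    message("dropping topology rows for ", length(bad),
            " accession(s) absent from the database")
    df <- df[df$accession %in% names(proteins), , drop = FALSE]
  }
  if (!all(df$label %in% .TOPOLOGY_LABELS)) {
    stop("unknown topology label(s): ",
         paste(setdiff(unique(df$label), .TOPOLOGY_LABELS), collapse = ", "),
         call. = FALSE)
  }
  lens <- Biostrings::width(proteins)[match(df$accession, names(proteins))]
  bad <- is.na(df$start) | is.na(df$end) | df$start < 1L |
    df$start > df$end | df$end > lens
  if (any(bad)) {
    stop("topology region out of range for: ",
         paste(sprintf("%s[%s-%s]", df$accession[bad], df$start[bad],
                       df$end[bad]), collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$accession, df$predictor, df$start), , drop = FALSE]
  by <- split(seq_len(nrow(df)), paste(df$accession, df$predictor, sep = "\r"))
  for (idx in by) {
    if (length(idx) > 1L &&
        any(df$start[idx][-1L] <= df$end[idx][-length(idx)])) {
      stop("overlapping regions for ", df$accession[idx[1L]], " / ",
           df$predictor[idx[1L]], call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Read surface-prediction consensus and signal-peptide calls
#'
#' Loads the per-protein surface-prediction consensus (SPC) score, an integer
#' 0-4 counting independent resources that predict surface localization, plus
#' up to three boolean signal-peptide calls from sequence-based predictors.
#' Proteins absent from the table default to the worst case: SPC 0 and no
#' signal peptide (reported via a message).
#'
#' @param path TSV with columns `accession`, `spc_score`, and up to three
#'   boolean columns whose names start with `sp_` (one per predictor).
#' @param proteins `AAStringSet` the annotations refer to.
#' @return A `data.frame` with one row per protein in `proteins`: `accession`,
#'   `spc_score`, logical `sp_1..sp_3` (NA where a predictor made no call).
#' @export
readSurfacePredictions <- function(path, proteins) {
  df <- readTsv(path, required = c("accession", "spc_score"))
  spCols <- grep("^sp_", colnames(df), value = TRUE)
  if (length(spCols) > 3L) {
    stop("at most three signal-peptide predictor columns (sp_*) are supported",
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$accession), names(proteins))
  if (length(unknown)) {
    stop("surface predictions reference unknown accession(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$accession)) {
    stop("duplicate accession(s) in surface-prediction table", call. = FALSE)
  }
  spc <- suppressWarnings(as.integer(df$spc_score))
  if (any(is.na(spc) | spc < 0L | spc > 4L)) {
    stop("spc_score must be an integer in 0..4; offending accession(s): ",
         paste(df$accession[is.na(spc) | spc < 0L | spc > 4L],
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(accession = names(proteins),
                    spc_score = 0L,
                    sp_1 = NA, sp_2 = NA, sp_3 = NA,
                    stringsAsFactors = FALSE)
  i <- match(df$accession, out$accession)
  out$spc_score[i] <- spc
  for (k in seq_along(spCols)) {
    out[[paste0("sp_", k)]][i] <- parseBool(df[[spCols[k]]],
                                            what = "signal-peptide")
  }
  nDefault <- sum(!(out$accession %in% df$accession))
  if (nDefault > 0L) {
    message(nDefault, " protein(s) absent from the surface-prediction table; ",
            "defaulting to SPC 0 and no signal peptide")
  }
  rownames(out) <- NULL
  out
}

#' Reduce signal-peptide predictor calls to one flag per protein
#'
#' @param surfacePred Table from [readSurfacePredictions()].
#' @param rule `"any"` (default; one positive predictor suffices) or
#'   `"majority"` (at least two of three positive).
#' @return Named logical vector, one element per protein.
#' @export
signalPeptideCall <- function(surfacePred, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  calls <- as.matrix(surfacePred[, c("sp_1", "sp_2", "sp_3"), drop = FALSE])
  npos <- rowSums(calls == TRUE, na.rm = TRUE)
  flag <- if (rule == "any") npos >= 1L else npos >= 2L
  names(flag) <- surfacePred$accession
  flag
}
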