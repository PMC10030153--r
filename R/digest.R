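## Monoisotopic residue masses (Da), standard atomic masses.
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.MASS_WATER  <- 18.010565
.MASS_PROTON <- 1.007276

#' Mass deltas of the modifications the package recognizes by name
#' @keywords internal
.MOD_DELTAS <- c(Carbamidomethyl = 57.02146,
                 Deamidated      = 0.98402,
                 Oxidation       = 15.99491)

#' In-silico digestion with a combined trypsin/Lys-C rule
#'
#' Cleaves after every K (Lys-C ignores the proline rule) and after every R
#' not followed by P (trypsin rule). At 0 missed cleavages the peptides tile
#' the sequence; products with up to `missedCleavages` internal retained sites
#' are concatenations of adjacent fully cleaved peptides.
#'
#' @param sequence Amino-acid string (one protein).
#' @param missedCleavages Maximum number of missed cleavage sites (>= 0).
#' @return A `data.frame` with columns `start`, `end` (1-based inclusive
#'   protein coordinates), `sequence` and `missed_cleavages`.
#' @examples
#' digestProtein("AKRPGKR")            # AK, RPGK, R
#' digestProtein("AKGK", missedCleavages = 1)
#' @export
digestProtein <- function(sequence, missedCleavages = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  if (missedCleavages < 0L) stop("missedCleavages must be >= 0", call. = FALSE)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  ## cleavage site after position i: K always; R unless next residue is P
  cut <- which((res == "K") | (res == "R" & c(res[-1L], "") != "P"))
  cut <- cut[cut < n]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  k <- length(starts)
  rows <- vector("list", as.integer(missedCleavages) + 1L)
  for (mc in 0:missedCleavages) {
    if (k - mc < 1L) break
    i <- seq_len(k - mc)
    rows[[mc + 1L]] <- data.frame(start = starts[i], end = ends[i + mc],
                                  missed_cleavages = mc)
  }
  out <- do.call(rbind, rows)
  out$sequence <- substring(sequence, out$start, out$end)
  out <- out[order(out$start, out$end), c("start", "end", "sequence",
                                          "missed_cleavages")]
  rownames(out) <- NULL
  out
}

#' Find N-glycosylation sequons (SCM sites)
#'
#' Scans a sequence for the sequence consensus motif N-X-S/T (X != P), the
#' sequon to which N-glycans attach; optionally also the rarer N-X-C sequon.
#' A window containing the unknown residue X never matches (conservative
#' motif calling). Positions within two residues of the C-terminus cannot
#' host a complete motif.
#'
#' @param sequence Amino-acid string.
#' @param includeNxc Also report N-X-C sequons (default `FALSE`).
#' @return `data.frame` with columns `position` (of the N, 1-based), `motif`
#'   (the 3-residue window) and `motif_class` (`NxS`, `NxT` or `NxC`).
#' @examples
#' findScmSites("ANGSA")   # N-G-S at position 2
#' findScmSites("ANPSA")   # none: X = P
#' @export
findScmSites <- function(sequence, includeNxc = FALSE) {
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(res)
  empty <- data.frame(position = integer(), motif = character(),
                      motif_class = character(), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  p <- seq_len(n - 2L)
  third <- res[p + 2L]
  ok <- res[p] == "N" & res[p + 1L] != "P" & res[p + 1L] != "X" &
    (third %in% c("S", "T") | (includeNxc & third == "C"))
  p <- p[ok]
  if (!length(p)) return(empty)
  data.frame(position = p,
             motif = paste0(res[p], res[p + 1L], res[p + 2L]),
             motif_class = paste0("Nx", res[p + 2L]),
             stringsAsFactors = FALSE)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus modification
#' deltas. Carbamidomethylation of cysteine (+57.02146 Da, from iodoacetamide
#' alkylation) is applied as the default fixed modification; deamidation
#' (+0.98402 Da) is available as a variable modification by name.
#'
#' @param sequence Peptide string; the unknown residue X has no mass and is an
#'   error.
#' @param fixedMods Named numeric vector: residue letter -> delta Da applied
#'   to every occurrence. Default carbamidomethyl-C.
#' @param variableMods Numeric vector of per-peptide deltas to add (e.g. one
#'   `+0.98402` per deamidated residue), default none.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptideMass("GG")                       # 132.05349
#' peptideMass("C")                        # includes carbamidomethyl
#' @export
peptideMass <- function(sequence, fixedMods = c(C = 57.02146),
                        variableMods = numeric()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  m <- .RESIDUE_MASS[res]
  if (anyNA(m)) {
    stop("no monoisotopic mass for residue(s): ",
         paste(unique(res[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(c(fixedMods, variableMods)))) {
    stop("modification deltas must be finite", call. = FALSE)
  }
  fixed <- 0
  if (length(fixedMods)) {
    cnt <- vapply(names(fixedMods), function(r) sum(res == r), integer(1))
    fixed <- sum(cnt * fixedMods)
  }
  sum(m) + .MASS_WATER + fixed + sum(variableMods)
}

#' Mass-to-charge ratio
#'
#' `(mass + z * 1.007276) / z` for a positive ion of charge `z`.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Charge state (integer >= 1).
#' @return m/z value(s); vectorized over `mass`.
#' @export
massToMz <- function(mass, z) {
  if (any(z < 1)) stop("charge state must be >= 1", call. = FALSE)
  (mass + z * .MASS_PROTON) / z
}

#' MS detectability of a tryptic peptide
#'
#' A peptide is considered detectable when it has more than five amino acids
#' (length >= 6) and its 2+ or 3+ charge-state m/z falls below 2,000 -- the
#' constraints used for in-silico detectability scoring of extracellular SCM
#' peptides. There is no lower m/z bound.
#'
#' @param sequence Peptide string(s).
#' @param fixedMods Passed to [peptideMass()].
#' @return `data.frame` with `sequence`, `monoisotopic_mass`, `mz2`, `mz3`,
#'   `detectable` and `failure_reason` (`NA` when detectable; `"length"` or
#'   `"mz"` otherwise, length checked first).
#' @export
assessDetectability <- function(sequence, fixedMods = c(C = 57.02146)) {
  mass <- vapply(sequence, peptideMass, numeric(1), fixedMods = fixedMods,
                 USE.NAMES = FALSE)
  mz2 <- massToMz(mass, 2L)
  mz3 <- massToMz(mass, 3L)
  len <- nchar(sequence)
  detectable <- len >= 6L & pmin(mz2, mz3) < 2000
  reason <- rep(NA_character_, length(sequence))
  reason[len < 6L] <- "length"
  reason[len >= 6L & !detectable] <- "mz"
  data.frame(sequence = sequence, monoisotopic_mass = mass,
             mz2 = mz2, mz3 = mz3, detectable = detectable,
             failure_reason = reason, stringsAsFactors = FALSE)
}
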