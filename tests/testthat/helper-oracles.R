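# Independent re-derivations used to cross-check the implementation.
# These deliberately take different routes than the package code.

# Position-scan cleavage oracle: regex lookahead finds every cleavage site
# (after K always, after R unless P follows), then peptides are rebuilt by
# concatenating adjacent fully cleaved fragments.
oracleDigest <- function(sequence, missedCleavages = 0L) {
  sites <- gregexpr("K|R(?!P)", sequence, perl = TRUE)[[1L]]
  sites <- as.integer(sites[sites > 0])
  n <- nchar(sequence)
  sites <- sites[sites < n]
  bounds <- c(0L, sites, n)
  frags <- data.frame(start = head(bounds, -1L) + 1L, end = bounds[-1L])
  out <- list()
  for (mc in 0:missedCleavages) {
    k <- nrow(frags) - mc
    if (k < 1L) break
    for (i in seq_len(k)) {
      out[[length(out) + 1L]] <- data.frame(
        start = frags$start[i], end = frags$end[i + mc],
        missed_cleavages = mc)
    }
  }
  res <- do.call(rbind, out)
  res$sequence <- substring(sequence, res$start, res$end)
  res[order(res$start, res$end), c("start", "end", "sequence",
                                   "missed_cleavages")]
}

# Sequon-scan oracle: literal per-position window check.
oracleScm <- function(sequence, includeNxc = FALSE) {
  n <- nchar(sequence)
  hits <- integer()
  for (i in seq_len(max(0L, n - 2L))) {
    w <- substr(sequence, i, i + 2L)
    a <- substr(w, 1L, 1L); b <- substr(w, 2L, 2L); c3 <- substr(w, 3L, 3L)
    if (a == "N" && b != "P" && b != "X" &&
        (c3 %in% c("S", "T") || (includeNxc && c3 == "C"))) {
      hits <- c(hits, i)
    }
  }
  hits
}

# Elemental-composition mass oracle: residue masses rebuilt from atom counts
# and monoisotopic atomic masses, independent of the package's residue table.
oracleMass <- local({
  atoms <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
             O = 15.9949146221, S = 31.97207069)
  comp <- list(  #     C  H  N  O  S
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  resMass <- vapply(comp, function(x)
    sum(x * atoms[c("C", "H", "N", "O", "S")]), numeric(1))
  water <- 2 * atoms[["H"]] + atoms[["O"]]
  cam <- sum(c(2, 3, 1, 1, 0) * atoms[c("C", "H", "N", "O", "S")])  # C2H3NO
  function(sequence, carbamidomethyl = TRUE) {
    r <- strsplit(sequence, "")[[1L]]
    sum(resMass[r]) + water +
      if (carbamidomethyl) sum(r == "C") * cam else 0
  }
})

# Brute-force pairwise Gini.
oracleGini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Benjamini-Hochberg step-up by hand.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

randomPeptide <- function(len) {
  paste(sample(names(glycoCSC:::.RESIDUE_MASS), len, replace = TRUE),
        collapse = "")
}

randomSequence <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

writeFasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names(records)), records)), path)
  path
}

# Minimal generic-dialect PSM table on disk.
writePsmTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
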