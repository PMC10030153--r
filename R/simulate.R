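## Residue pools for synthetic sequences. The planted-truth design needs
## control over where sequons can occur, so background residues exclude N
## (and K/R/P inside planted peptides, to fix tryptic boundaries).
.BG_RESIDUES <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "Q", "S", "T",
                  "V", "W", "Y", "K", "R", "P", "C")
.BG_WEIGHTS <- c(8, 5, 6, 4, 7, 2, 5, 9, 2, 4, 7, 6, 7, 1, 3, 5, 5, 5, 2)
.PLANT_POOL <- c("A", "D", "E", "F", "G", "L", "S", "T", "V")  # no K/R/N/P

.randomSeq <- function(n, includeN = FALSE) {
  pool <- .BG_RESIDUES
  w <- .BG_WEIGHTS
  if (includeN) {
    pool <- c(pool, "N")
    w <- c(w, 4)
  }
  paste(sample(pool, n, replace = TRUE, prob = w), collapse = "")
}

## A planted detectable sequon peptide: length 8, N at position 3, sequon
## N-x-S/T, C-terminal K, no internal K/R/P, preceded in the protein by K.
.plantPeptide <- function() {
  x <- sample(setdiff(.PLANT_POOL, "P"), 1L)
  st <- sample(c("S", "T"), 1L)
  body <- sample(.PLANT_POOL, 4L, replace = TRUE)
  paste0(paste(body[1:2], collapse = ""), "N", x, st,
         paste(body[3:4], collapse = ""), "K")
}

#' Generate a synthetic proteome with planted surface truth
#'
#' Builds a FASTA database plus topology and surface-prediction tables in
#' which every protein's surface status, and the classifier branch that
#' should detect it, is known by construction. Surface proteins are split
#' across the three decision branches (60% detectable-extracellular-sequon,
#' 25% surface-prediction consensus, 15% signal peptide); each carries
#' exactly the annotation its branch requires and none that would trip an
#' earlier branch. Non-surface proteins get no extracellular exposure, SPC
#' <= 2 and no signal peptide. Sequon placement is controlled by excluding
#' asparagine from background residues except where a sequon is planted.
#'
#' @param n Number of proteins (>= 1).
#' @param surfaceFraction Fraction classified surface (0-1, default 0.5).
#' @param seed Integer RNG seed; the bundle is a pure function of
#'   `(parameters, seed)`.
#' @param dir Output directory (created if needed).
#' @param branchMix Probabilities for the three surface branches, in order
#'   (cirfess, spc, signal peptide).
#' @return A fixture bundle list: paths `fasta`, `topology`,
#'   `surface_predictions`, `truth`, and the `truth` object itself
#'   (per-protein `accession`, `is_surface`, `branch`, planted peptide and
#'   sequon position where applicable).
#' @export
generateProteome <- function(n, surfaceFraction = 0.5, seed = 1L,
                             dir = tempfile("fixture"),
                             branchMix = c(0.6, 0.25, 0.15)) {
  stopifnot(n >= 1L, surfaceFraction >= 0, surfaceFraction <= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  nSurface <- round(n * surfaceFraction)
  branch <- c(sample(c("cirfess_positive", "spc_consensus", "signal_peptide"),
                     nSurface, replace = TRUE, prob = branchMix),
              rep("none", n - nSurface))
  acc <- sprintf("SYN%04d", seq_len(n))
  seqs <- character(n)
  topo <- list()
  surf <- list()
  truth <- list()
  for (i in seq_len(n)) {
    L <- sample(250:500, 1L)
    b <- branch[i]
    rec <- list(accession = acc[i], is_surface = b != "none", branch = b,
                planted_peptide = NA_character_, scm_position = NA_integer_)
    if (b == "cirfess_positive") {
      extEnd <- sample(60:120, 1L)
      pep <- .plantPeptide()
      s <- sample(5:(extEnd - nchar(pep)), 1L)
      if (s + nchar(pep) - 1L > extEnd) stop("infeasible sequon placement")
      pre <- .randomSeq(s - 2L)
      post <- .randomSeq(L - (s + nchar(pep) - 1L))
      seqs[i] <- paste0(pre, "K", pep, post)
      stopifnot(nchar(seqs[i]) == L)
      rec$planted_peptide <- pep
      rec$scm_position <- s + 2L
      topo[[length(topo) + 1L]] <- data.frame(
        accession = acc[i], predictor = "predictor-A",
        start = c(1L, extEnd + 1L, extEnd + 22L),
        end = c(extEnd, extEnd + 21L, L),
        label = c("extracellular", "transmembrane", "cytoplasmic"),
        stringsAsFactors = FALSE)
      surf[[length(surf) + 1L]] <- data.frame(
        accession = acc[i], spc_score = sample(0:2, 1L),
        sp_predictor1 = FALSE, sp_predictor2 = FALSE, sp_predictor3 = FALSE,
        stringsAsFactors = FALSE)
    } else if (b == "spc_consensus") {
      seqs[i] <- .randomSeq(L)
      topo[[length(topo) + 1L]] <- data.frame(
        accession = acc[i], predictor = "predictor-A",
        start = c(1L, 41L, 62L), end = c(40L, 61L, L),
        label = c("extracellular", "transmembrane", "cytoplasmic"),
        stringsAsFactors = FALSE)
      surf[[length(surf) + 1L]] <- data.frame(
        accession = acc[i], spc_score = sample(3:4, 1L),
        sp_predictor1 = FALSE, sp_predictor2 = FALSE, sp_predictor3 = FALSE,
        stringsAsFactors = FALSE)
    } else if (b == "signal_peptide") {
      seqs[i] <- .randomSeq(L)
      topo[[length(topo) + 1L]] <- data.frame(
        accession = acc[i], predictor = "predictor-A",
        start = 1L, end = sample(18:26, 1L), label = "signal_peptide",
        stringsAsFactors = FALSE)
      calls <- rep(FALSE, 3L)
      calls[sample.int(3L, sample(1:3, 1L))] <- TRUE
      surf[[length(surf) + 1L]] <- data.frame(
        accession = acc[i], spc_score = sample(0:2, 1L),
        sp_predictor1 = calls[1L], sp_predictor2 = calls[2L],
        sp_predictor3 = calls[3L], stringsAsFactors = FALSE)
    } else {
      seqs[i] <- .randomSeq(L, includeN = TRUE)
      if (stats::runif(1) < 0.5) {
        topo[[length(topo) + 1L]] <- data.frame(
          accession = acc[i], predictor = "predictor-A",
          start = 1L, end = L, label = "cytoplasmic",
          stringsAsFactors = FALSE)
      }
      surf[[length(surf) + 1L]] <- data.frame(
        accession = acc[i], spc_score = sample(0:2, 1L),
        sp_predictor1 = FALSE, sp_predictor2 = FALSE, sp_predictor3 = FALSE,
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- rec
  }
  fastaPath <- file.path(dir, "proteome.fasta")
  lines <- as.vector(rbind(paste0(">", acc, " synthetic protein"), seqs))
  writeLines(lines, fastaPath)
  topoPath <- file.path(dir, "topology.tsv")
  writeTsv(do.call(rbind, topo), topoPath)
  surfPath <- file.path(dir, "surface_predictions.tsv")
  sp <- do.call(rbind, surf)
  colnames(sp) <- c("accession", "spc_score", "sp_predisi", "sp_signalp",
                    "sp_phobius")
  writeTsv(sp, surfPath)
  truthDf <- do.call(rbind, lapply(truth, as.data.frame))
  truthPath <- file.path(dir, "truth_proteome.json")
  jsonlite::write_json(truthDf, truthPath, digits = NA)
  list(dir = dir, fasta = fastaPath, topology = topoPath,
       surface_predictions = surfPath, truth_path = truthPath,
       truth = truthDf,
       params = list(n = n, surfaceFraction = surfaceFraction, seed = seed))
}

#' Generate a synthetic PSM table against a fixture proteome
#'
#' Emits `nPsms` peptide-spectrum matches: a binomial fraction
#' `scmSpecificity` are deamidated at a planted true sequon (the signature
#' of captured glycopeptides), the remainder are background tryptic peptides
#' without sequon evidence -- a fraction `deamidationRate` of those carry a
#' spurious deamidation on an asparagine verified to sit outside any sequon,
#' exercising the motif check.
#'
#' @param bundle Result of [generateProteome()].
#' @param nPsms Number of PSMs (>= 1).
#' @param scmSpecificity Probability a PSM is true sequon evidence (0-1).
#' @param deamidationRate Spurious-deamidation probability for background
#'   PSMs (default 0.1).
#' @param seed Integer RNG seed.
#' @return Path of the written PSM TSV (generic dialect), with the truth
#'   attribute `"n_scm"` (number of true sequon PSMs emitted).
#' @export
generatePsmTable <- function(bundle, nPsms, scmSpecificity,
                             deamidationRate = 0.1, seed = 1L) {
  if (nPsms < 1L) stop("nPsms must be >= 1", call. = FALSE)
  set.seed(seed)
  proteins <- readProteome(bundle$fasta)
  truth <- bundle$truth
  scmDonors <- truth[!is.na(truth$planted_peptide), , drop = FALSE]
  isScm <- stats::rbinom(nPsms, 1L, scmSpecificity) == 1L
  if (any(isScm) && !nrow(scmDonors)) {
    stop("no sequon-bearing proteins in the bundle", call. = FALSE)
  }
  ## background candidates: detectable-length tryptic peptides anywhere
  bgPool <- do.call(rbind, lapply(names(proteins), function(a) {
    d <- digestProtein(as.character(proteins[[a]]))
    d <- d[nchar(d$sequence) >= 6L, , drop = FALSE]
    if (nrow(d)) cbind(accession = a, d) else NULL
  }))
  rows <- vector("list", nPsms)
  for (i in seq_len(nPsms)) {
    if (isScm[i]) {
      j <- sample.int(nrow(scmDonors), 1L)
      pep <- scmDonors$planted_peptide[j]
      mods <- "3|Deamidated|0.98402"   # planted sequon N is position 3
      accs <- scmDonors$accession[j]
    } else {
      j <- sample.int(nrow(bgPool), 1L)
      pep <- bgPool$sequence[j]
      accs <- bgPool$accession[j]
      mods <- ""
      if (stats::runif(1) < deamidationRate) {
        npos <- which(strsplit(pep, "")[[1L]] == "N")
        if (length(npos)) {
          protSeq <- as.character(proteins[[accs]])
          protPos <- bgPool$start[j] + npos - 1L
          ## only deamidate an N whose protein-context window is NOT a sequon
          ok <- vapply(protPos, function(p) {
            win <- substring(protSeq, p, p + 2L)
            !nrow(findScmSites(win)) || findScmSites(win)$position[1L] != 1L
          }, logical(1))
          if (any(ok)) {
            p <- npos[ok][sample.int(sum(ok), 1L)]
            mods <- sprintf("%d|Deamidated|0.98402", p)
          }
        }
      }
    }
    rows[[i]] <- data.frame(
      spectrum_id = sprintf("PSM%06d", i), peptide = pep,
      modifications = mods, proteins = accs,
      intensity = round(2^stats::rnorm(1, 20, 1.5), 1), run = "run1",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  path <- file.path(bundle$dir, "psms.tsv")
  writeTsv(out, path)
  attr(path, "n_scm") <- sum(isScm)
  path
}

#' Generate a synthetic intensity matrix with planted group effects
#'
#' Simulates log2 feature intensities as protein mean + feature offset + run
#' shift + group effect (for the differential proteins) + gaussian noise,
#' then applies left-censoring: entries below each feature's
#' `censorQuantile` quantile are set missing, mimicking below-detection-limit
#' dropout. Run shifts are drawn Normal(0, 0.5) so equalize-median
#' normalization has real work to do. Defaults mirror a two-condition
#' label-free comparison with three and four biological replicates.
#'
#' @param nProteins Number of proteins.
#' @param nFeaturesPerProtein Features (peptides) per protein (default 3).
#' @param groups Named integer vector: group name -> number of runs
#'   (default `c(nonfailing = 3, failing = 4)`).
#' @param effectLog2 Absolute log2 group effect for differential proteins
#'   (default 2); the sign is random per protein.
#' @param deFraction Fraction of proteins differential (default 0.1).
#' @param sigma Gaussian noise sd on the log2 scale (default 0.3).
#' @param censorQuantile Per-feature left-censoring quantile (default 0.15;
#'   0 = no missingness).
#' @param seed Integer RNG seed.
#' @param dir Output directory.
#' @return List: paths `intensity`, `design`, `truth_path`; `truth`
#'   `data.frame` (`protein`, `is_de`, `effect_log2`, `true_mean_log2`);
#'   `se`, the same data as a `SummarizedExperiment`.
#' @export
generateIntensityMatrix <- function(nProteins, nFeaturesPerProtein = 3L,
                                    groups = c(nonfailing = 3L, failing = 4L),
                                    effectLog2 = 2, deFraction = 0.1,
                                    sigma = 0.3, censorQuantile = 0.15,
                                    seed = 1L, dir = tempfile("quantfix")) {
  if (deFraction < 0 || deFraction > 1) {
    stop("deFraction must be in [0, 1]", call. = FALSE)
  }
  if (any(groups < 2L)) stop("need >= 2 runs per group", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  runs <- unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(groups[[g]]))))
  grp <- rep(names(groups), groups)
  nRuns <- length(runs)
  runShift <- stats::rnorm(nRuns, 0, 0.5)
  prot <- sprintf("PROT%04d", seq_len(nProteins))
  nDe <- round(nProteins * deFraction)
  deIdx <- sample.int(nProteins, nDe)
  effect <- numeric(nProteins)
  effect[deIdx] <- effectLog2 * sample(c(-1, 1), nDe, replace = TRUE)
  baseMean <- stats::rnorm(nProteins, 20, 2)
  nFeat <- nProteins * nFeaturesPerProtein
  featProt <- rep(seq_len(nProteins), each = nFeaturesPerProtein)
  featOff <- stats::rnorm(nFeat, 0, 1)
  isG2 <- grp == names(groups)[2L]
  mu <- outer(baseMean[featProt] + featOff, runShift, `+`) +
    outer(effect[featProt], as.numeric(isG2))
  m <- mu + matrix(stats::rnorm(nFeat * nRuns, 0, sigma), nFeat, nRuns)
  dimnames(m) <- list(sprintf("%s_f%d", prot[featProt],
                              rep(seq_len(nFeaturesPerProtein), nProteins)),
                      runs)
  if (censorQuantile > 0) {
    for (i in seq_len(nFeat)) {
      q <- stats::quantile(m[i, ], censorQuantile, names = FALSE)
      m[i, m[i, ] < q] <- NA_real_
    }
  }
  raw <- round(2^m, 4)
  intensity <- data.frame(protein = prot[featProt],
                          feature = rownames(m), stringsAsFactors = FALSE)
  intensity <- cbind(intensity, as.data.frame(raw))
  intensityPath <- file.path(dir, "intensity.tsv")
  writeTsv(intensity, intensityPath)
  design <- data.frame(run = runs, group = grp, replicate_set = grp,
                       stringsAsFactors = FALSE)
  designPath <- file.path(dir, "design.tsv")
  writeTsv(design, designPath)
  truth <- data.frame(protein = prot, is_de = seq_len(nProteins) %in% deIdx,
                      effect_log2 = effect, true_mean_log2 = baseMean,
                      stringsAsFactors = FALSE)
  truthPath <- file.path(dir, "truth_quant.json")
  jsonlite::write_json(truth, truthPath, digits = NA)
  se <- readIntensityMatrix(intensityPath, designPath)
  list(intensity = intensityPath, design = designPath,
       truth_path = truthPath, truth = truth, se = se,
       params = list(nProteins = nProteins, seed = seed))
}
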