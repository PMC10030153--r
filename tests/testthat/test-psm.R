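mkPsm <- function(peptide, mods = "", proteins = "P1",
                  id = sprintf("S%03d", seq_along(peptide))) {
  data.frame(spectrum_id = id, peptide = peptide, modifications = mods,
             proteins = proteins, stringsAsFactors = FALSE)
}

test_that("both PSM dialects parse modification strings", {
  p <- readPsmTable(writePsmTsv(mkPsm("AAANGTK", "4|Deamidated")))
  expect_equal(p$modifications[[1]]$position, 4L)
  expect_equal(p$modifications[[1]]$delta, 0.98402)
  ## explicit delta overrides the lookup
  p2 <- readPsmTable(writePsmTsv(mkPsm("AAANGTK", "4|Deamidated|0.984")))
  expect_equal(p2$modifications[[1]]$delta, 0.984)
  ## ProteomeDiscoverer-style
  pd <- readPsmTable(writePsmTsv(mkPsm(
    "AAANGTCK", "1xDeamidated [N4]; 1xCarbamidomethyl [C7]")), dialect = "pd")
  expect_equal(pd$modifications[[1]]$position, c(4L, 7L))
  expect_equal(pd$modifications[[1]]$name,
               c("Deamidated", "Carbamidomethyl"))
  expect_equal(pd$modifications[[1]]$delta[1], 0.98402)
  pd2 <- readPsmTable(writePsmTsv(mkPsm("AACCK", "2xCarbamidomethyl [C3; C4]")),
                      dialect = "pd")
  expect_equal(pd2$modifications[[1]]$position, c(3L, 4L))
  ## no modifications -> empty list
  expect_equal(nrow(readPsmTable(writePsmTsv(
    mkPsm("AAANGTK")))$modifications[[1]]), 0L)
})

test_that("schema and row-level PSM errors are reported", {
  bad <- data.frame(spectrum_id = "S1", modifications = "", proteins = "P1")
  expect_error(readPsmTable(writePsmTsv(bad)), "peptide")
  ## out-of-range modification position: row dropped with a count
  df <- mkPsm(c("AAANGTK", "AAANGTK"), c("4|Deamidated", "99|Deamidated"))
  expect_warning(p <- readPsmTable(writePsmTsv(df)), "1 PSM row")
  expect_equal(nrow(p), 1L)
})

test_that("sequon deamidation is evaluated in protein context", {
  prot <- readProteome(writeFasta(c(P1 = "MKAAANGTKLLR")))
  ## motif inside the peptide
  ev <- flagScmDeamidation(readPsmTable(writePsmTsv(
    mkPsm("AAANGTK", "4|Deamidated"))), prot)
  expect_equal(ev$position, 6L)
  expect_equal(ev$motif, "NGT")
  ## motif spanning the peptide C-terminus: peptide ends ...N, protein
  ## continues with G,T
  prot2 <- readProteome(writeFasta(c(P1 = "MKAAANGTK")))
  ev2 <- flagScmDeamidation(readPsmTable(writePsmTsv(
    mkPsm("AAAN", "4|Deamidated"))), prot2)
  expect_equal(ev2$position, 6L)
  expect_equal(ev2$motif, "NGT")
  ## proline in the X slot: no evidence
  prot3 <- readProteome(writeFasta(c(P1 = "MKAANPSKLL")))
  ev3 <- flagScmDeamidation(readPsmTable(writePsmTsv(
    mkPsm("AANPSK", "3|Deamidated"))), prot3)
  expect_equal(nrow(ev3), 0L)
  ## deamidation recognized by delta alone, on an N
  ev4 <- flagScmDeamidation(readPsmTable(writePsmTsv(
    mkPsm("AAANGTK", "4|unknown_mod|0.9843"))), prot)
  expect_equal(ev4$position, 6L)
  ## peptide absent from every listed protein
  expect_error(flagScmDeamidation(readPsmTable(writePsmTsv(
    mkPsm("WWWWWW"))), prot), "not found")
})

test_that("evidence never lands on a non-N residue", {
  set.seed(31)
  prot <- readProteome(writeFasta(c(P1 = randomSequence(120))))
  s <- as.character(prot[["P1"]])
  peps <- oracleDigest(s, 0)
  peps <- peps[nchar(peps$sequence) >= 4, ]
  residues <- character()
  for (i in seq_len(nrow(peps))) {
    pos <- sample(nchar(peps$sequence[i]), 1)
    ev <- flagScmDeamidation(readPsmTable(writePsmTsv(
      mkPsm(peps$sequence[i], sprintf("%d|Deamidated", pos)))), prot)
    if (nrow(ev)) {
      residues <- c(residues, substring(s, ev$position, ev$position))
    }
  }
  expect_true(all(residues == "N"))
})

test_that("master proteins are resolved by peptide uniqueness", {
  prot <- readProteome(writeFasta(c(
    P1 = "MKAAANGTKLLRGGGWWK",  # has unique peptide GGGWWK
    P2 = "MKAAANGTKLLR",        # all peptides shared with P1
    P3 = "QQQWWKAAACCK")))      # independent
  psms <- readPsmTable(writePsmTsv(mkPsm(
    c("AAANGTK", "GGGWWK", "AAACCK"),
    proteins = c("P1;P2", "P1", "P3"))))
  res <- assignMasterProteins(psms, prot)
  expect_setequal(res$masters$accession, c("P1", "P3"))
  expect_equal(res$masters$grouped_accessions[
    res$masters$accession == "P1"], "P2")
  ## shared peptide counts under its master only
  expect_equal(res$psmMasters[[1]], "P1")
  ## identical peptide sets collapse to the lexicographically smallest
  prot2 <- readProteome(writeFasta(c(PB = "MKAAANGTK", PA = "MKAAANGTK")))
  res2 <- assignMasterProteins(readPsmTable(writePsmTsv(
    mkPsm("AAANGTK", proteins = "PA;PB"))), prot2)
  expect_equal(res2$masters$accession, "PA")
  expect_equal(res2$masters$grouped_accessions, "PB")
  empty <- data.frame(spectrum_id = character(), peptide = character(),
                      stringsAsFactors = FALSE)
  expect_error(assignMasterProteins(empty, prot), "empty")
})

test_that("capture specificity is the SCM fraction of PSMs and proteins", {
  prot <- readProteome(writeFasta(c(
    P1 = "MKAAANGTKLLR", P2 = "MKWWWGGGKLLR", P3 = "MKCCCDDDKLLR",
    P4 = "MKEEEFFFKLLR")))
  pep <- c("AAANGTK", "WWWGGGK", "CCCDDDK", "EEEFFFK")
  ## 10 PSMs: 8 sequon-deamidated on P1, 2 unmodified on P2..P4-ish
  psms <- readPsmTable(writePsmTsv(mkPsm(
    c(rep("AAANGTK", 8), "WWWGGGK", "CCCDDDK"),
    mods = c(rep("4|Deamidated", 8), "", ""),
    proteins = c(rep("P1", 8), "P2", "P3"))))
  ev <- flagScmDeamidation(psms, prot)
  ma <- assignMasterProteins(psms, prot)
  sp <- computeSpecificity(psms, ev, ma)
  expect_equal(sp$psm_level$percent, 80)
  expect_equal(sp$psm_level$numerator, 8L)
  ## protein level: 1 of 3 masters carries sequon evidence
  expect_equal(sp$protein_level$denominator, 3L)
  expect_equal(sp$protein_level$percent, 100 / 3)
  ## all PSMs sequon-deamidated -> 100 exactly
  all8 <- readPsmTable(writePsmTsv(mkPsm(rep("AAANGTK", 5),
                                         mods = "4|Deamidated",
                                         proteins = "P1")))
  spAll <- computeSpecificity(all8, flagScmDeamidation(all8, prot),
                              assignMasterProteins(all8, prot))
  expect_identical(spAll$psm_level$percent, 100)
  expect_error(computeSpecificity(psms[0, ], ev, ma), "no PSMs")
})
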