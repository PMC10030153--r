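# Brute-force enumeration oracle for the detectability score of one protein:
# digest x sequon scan x filters, with an explicit extracellular residue set.
oracleCirfess <- function(seq, extResidues, missedCleavages = 0L) {
  peps <- oracleDigest(seq, missedCleavages)
  sites <- oracleScm(seq)
  sites <- sites[sites %in% extResidues]
  hits <- 0L
  for (i in seq_len(nrow(peps))) {
    has <- any(sites >= peps$start[i] & sites <= peps$end[i])
    if (!has) next
    p <- peps$sequence[i]
    mass <- oracleMass(p)
    if (nchar(p) >= 6L && (mass + 3 * 1.007276) / 3 < 2000) hits <- hits + 1L
  }
  hits
}

mkTopo <- function(acc, start, end, label, predictor = "predictor-A") {
  data.frame(accession = acc, predictor = predictor, start = start,
             end = end, label = label, stringsAsFactors = FALSE)
}

test_that("proteins without usable extracellular sequons score zero", {
  prot <- readProteome(writeFasta(c(P1 = strrep("AG", 50))))
  topo <- mkTopo("P1", 1, 40, "extracellular")
  r <- cirfessScore(prot, topo)
  expect_equal(cirfessScores(r)$score, 0L)
  expect_equal(nrow(contributingPeptides(r)), 0L)
  ## sequon present but only in a cytoplasmic region
  seq2 <- paste0(strrep("A", 60), "KLLNGSAVK", strrep("G", 31))
  prot2 <- readProteome(writeFasta(c(P2 = seq2)))
  topo2 <- rbind(mkTopo("P2", 1, 40, "extracellular"),
                 mkTopo("P2", 41, 60, "transmembrane"),
                 mkTopo("P2", 61, 100, "cytoplasmic"))
  expect_equal(cirfessScores(cirfessScore(prot2, topo2))$score, 0L)
})

test_that("a detectable extracellular sequon peptide scores one", {
  seq <- paste0("MK", "LLNGSAVK", strrep("A", 30), "K", strrep("G", 20))
  prot <- readProteome(writeFasta(c(P1 = seq)))
  topo <- mkTopo("P1", 1, 40, "extracellular")
  r <- cirfessScore(prot, topo)
  expect_equal(cirfessScores(r)$score, 1L)
  pep <- contributingPeptides(r)
  expect_equal(pep$sequence, "LLNGSAVK")
  expect_equal(pep$scm_position, 5L)
  expect_equal(pep$motif, "NGS")
  expect_true(validObject(r))
  ## matches the full enumeration oracle
  expect_equal(cirfessScores(r)$score, oracleCirfess(seq, 1:40))
})

test_that("scores agree with the enumeration oracle on random proteins", {
  set.seed(19)
  for (i in 1:30) {
    seq <- randomSequence(sample(80:250, 1))
    extEnd <- sample(30:70, 1)
    mc <- sample(0:1, 1)
    prot <- readProteome(writeFasta(c(PX = seq)))
    topo <- mkTopo("PX", 1, extEnd, "extracellular")
    got <- cirfessScores(cirfessScore(prot, topo,
                                      missedCleavages = mc))$score
    expect_equal(got, oracleCirfess(seq, seq_len(extEnd), mc), info = seq)
  }
})

test_that("score is monotone as the extracellular region grows", {
  set.seed(23)
  for (i in 1:10) {
    seq <- randomSequence(200)
    prot <- readProteome(writeFasta(c(PX = seq)))
    prev <- -1L
    for (extEnd in c(20, 60, 120, 200)) {
      s <- cirfessScores(cirfessScore(prot, mkTopo("PX", 1, extEnd,
                                                   "extracellular")))$score
      expect_gte(s, prev)
      prev <- s
    }
  }
})

test_that("multi-predictor topology is combined by union", {
  seq <- paste0("MK", "LLNGSAVK", strrep("A", 40))
  prot <- readProteome(writeFasta(c(P1 = seq)))
  ## predictor-A calls the sequon region cytoplasmic, predictor-B
  ## extracellular: one positive predictor suffices
  topo <- rbind(mkTopo("P1", 1, 50, "cytoplasmic", "predictor-A"),
                mkTopo("P1", 1, 20, "extracellular", "predictor-B"))
  expect_equal(cirfessScores(cirfessScore(prot, topo))$score, 1L)
})

test_that("signal peptide without transmembrane exposes the mature chain", {
  seq <- paste0(strrep("L", 20), "K", "LLNGSAVK", strrep("A", 21))
  prot <- readProteome(writeFasta(c(P1 = seq)))
  topo <- mkTopo("P1", 1, 20, "signal_peptide")
  r <- cirfessScore(prot, topo)
  expect_equal(cirfessScores(r)$score, 1L)
  expect_equal(cirfessScores(r)$topology_source, "signal_peptide")
  ## same protein with a transmembrane segment: no blanket exposure
  topo2 <- rbind(topo, mkTopo("P1", 40, 50, "transmembrane"))
  expect_equal(cirfessScores(cirfessScore(prot, topo2))$score, 0L)
  ## signal peptide known only from predictor calls, no topology at all
  sp <- data.frame(accession = "P1", spc_score = 0L, sp_1 = TRUE,
                   sp_2 = FALSE, sp_3 = NA)
  expect_equal(cirfessScores(cirfessScore(prot, surfacePred = sp))$score, 1L)
  ## no topology, no signal peptide: zero extracellular residues
  expect_equal(cirfessScores(cirfessScore(prot))$score, 0L)
})
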