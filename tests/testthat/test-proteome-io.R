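test_that("FASTA read/write roundtrip preserves records and uppercases", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 first protein", "mkngsavllk", ">P2", "ACDEFGHIK"), fa)
  prot <- readProteome(fa)
  expect_identical(names(prot), c("P1", "P2"))
  expect_identical(as.character(prot[["P1"]]), "MKNGSAVLLK")
  expect_identical(S4Vectors::mcols(prot)$description,
                   c("first protein", ""))
  out <- tempfile(fileext = ".fasta")
  writeProteome(prot, out)
  again <- readProteome(out)
  expect_identical(names(again), names(prot))
  expect_identical(as.character(again), as.character(prot))
  expect_identical(S4Vectors::mcols(again)$description,
                   S4Vectors::mcols(prot)$description)
})

test_that("an extracellular epitope substring is locatable at its offset", {
  epitope <- "CLKLRLASLSQLRRL"
  seq <- paste0(strrep("A", 30), epitope, strrep("G", 20))
  prot <- readProteome(writeFasta(c(LSM = seq)))
  hit <- regexpr(epitope, as.character(prot[["LSM"]]), fixed = TRUE)
  expect_equal(as.integer(hit), 31L)
  expect_equal(attr(hit, "match.length"), nchar(epitope))
})

test_that("invalid FASTA content is rejected", {
  expect_error(readProteome(writeFasta(c(P1 = "MKK", P1 = "MRR"))),
               "duplicate accession")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKK", ">P2", ""), fa)
  expect_error(readProteome(fa), "empty sequence")
  expect_error(suppressWarnings(readProteome(writeFasta(c(P1 = "MKBZ")))),
               "alphabet")
  notfa <- tempfile()
  writeLines("accession\tvalue", notfa)
  expect_error(readProteome(notfa))
})

test_that("topology tables are validated against the database", {
  prot <- readProteome(writeFasta(c(P1 = strrep("A", 100))))
  tsv <- tempfile(fileext = ".tsv")
  writeTab <- function(df) {
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    tsv
  }
  ok <- data.frame(accession = "P1", predictor = "predictor-A",
                   start = 50, end = 70, label = "transmembrane")
  topo <- readTopology(writeTab(ok), prot)
  expect_equal(nrow(topo), 1L)
  expect_error(readTopology(writeTab(transform(ok, start = 90, end = 120)),
                            prot), "out of range")
  expect_error(readTopology(writeTab(transform(ok, label = "outer_space")),
                            prot), "unknown topology label")
  two <- rbind(ok, transform(ok, predictor = "predictor-B", start = 45,
                             end = 72))
  both <- readTopology(writeTab(two), prot)
  expect_setequal(both$predictor, c("predictor-A", "predictor-B"))
  overlap <- rbind(ok, transform(ok, start = 60, end = 80,
                                 label = "extracellular"))
  expect_error(readTopology(writeTab(overlap), prot), "overlapping")
  expect_error(readTopology(writeTab(transform(ok, accession = "NOPE")),
                            prot), "unknown accession")
})

test_that("surface predictions load with worst-case defaults", {
  prot <- readProteome(writeFasta(c(P1 = "MKK", P2 = "MRR")))
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(accession = "P1", spc_score = 4, sp_a = "true",
                         sp_b = "false", sp_c = "true"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(sp <- readSurfacePredictions(tsv, prot), "defaulting")
  expect_equal(sp$spc_score[sp$accession == "P1"], 4L)
  expect_equal(sum(unlist(sp[sp$accession == "P1", c("sp_1", "sp_2", "sp_3")])
                   == TRUE, na.rm = TRUE), 2L)
  ## absent protein: SPC 0, no signal peptide
  expect_equal(sp$spc_score[sp$accession == "P2"], 0L)
  expect_false(signalPeptideCall(sp)[["P2"]])
  expect_true(signalPeptideCall(sp)[["P1"]])
  write.table(data.frame(accession = "P1", spc_score = 7),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSurfacePredictions(tsv, prot), "0..4")
  write.table(data.frame(accession = "P1", spc_score = 2, sp_a = "maybe"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSurfacePredictions(tsv, prot), "unparseable")
})

test_that("signal-peptide voting rules differ on single-predictor calls", {
  sp <- data.frame(accession = c("P1", "P2"), spc_score = 0L,
                   sp_1 = c(TRUE, TRUE), sp_2 = c(FALSE, TRUE),
                   sp_3 = c(NA, NA))
  expect_equal(unname(signalPeptideCall(sp, "any")), c(TRUE, TRUE))
  expect_equal(unname(signalPeptideCall(sp, "majority")), c(FALSE, TRUE))
})
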