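test_that("the surface decision rule fires the documented branches", {
  r <- classifySurface(cirfess = c(2, 0, 0, 0), spc = c(0, 3, 2, 0),
                       signalPeptide = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(r$branch, c("cirfess_positive", "spc_consensus", "none",
                           "signal_peptide"))
  expect_equal(r$is_surface, c(TRUE, TRUE, FALSE, TRUE))
  ## branch precedence: positive score wins over SPC and signal peptide
  both <- classifySurface(1, 4, TRUE)
  expect_equal(both$branch, "cirfess_positive")
  expect_error(classifySurface(0, 7, FALSE), "0..4")
  expect_error(classifySurface(-1, 0, FALSE), "non-negative")
})

test_that("classification equals exhaustive truth-table enumeration", {
  grid <- expand.grid(cirfess = c(0L, 1L), spc = 0:4,
                      sp = c(FALSE, TRUE))
  got <- classifySurface(grid$cirfess, grid$spc, grid$sp)
  ## independent literal transcription of the rule
  expected <- with(grid, (cirfess > 0) |
                     (cirfess == 0 & spc %in% c(3, 4)) |
                     (cirfess == 0 & sp))
  expect_equal(got$is_surface, expected)
  expect_equal(nrow(grid), 20L)
})

test_that("glycosite parity determines transmembrane orientation", {
  tm1 <- data.frame(start = 50, end = 70)
  v <- inferOrientation(c(30, 35), tm1, databaseOrientation = "N-out")
  expect_equal(v$orientation, "N-out")
  expect_equal(v$status, "consistent")
  ## sites on both sides of a single pass: impossible topology
  v2 <- inferOrientation(c(30, 90), tm1)
  expect_equal(v2$status, "conflict")
  expect_true(v2$conflicting)
  ## no glycosites
  expect_equal(inferOrientation(integer(), tm1)$orientation, "undetermined")
  ## database disagreement
  expect_equal(inferOrientation(30, tm1, "N-in")$status, "conflict")
  ## a site after an odd number of passes implies N-in
  tm2 <- data.frame(start = c(50, 100), end = c(70, 120))
  expect_equal(inferOrientation(85, tm2)$orientation, "N-in")
  expect_equal(inferOrientation(130, tm2)$orientation, "N-out")
  ## sites inside a transmembrane segment are excluded, not voted
  v3 <- inferOrientation(c(60, 30), tm1)
  expect_equal(v3$excluded_sites, 60L)
  expect_equal(v3$orientation, "N-out")
  expect_error(inferOrientation(30, tm1[0, ]), "transmembrane")
})

test_that("orientation is invariant to site order and duplicates", {
  tm <- data.frame(start = c(40, 90), end = c(60, 110))
  a <- inferOrientation(c(20, 70, 70, 20), tm)
  b <- inferOrientation(c(70, 20), tm)
  expect_identical(a, b)
})

test_that("the catalog separates SCM evidence from the filtered subset", {
  ## three proteins with sequon evidence; topology makes two classifiable
  prot <- readProteome(writeFasta(c(
    P1 = paste0("MK", "LLNGSAVK", strrep("A", 30)),
    P2 = paste0("MK", "TTNGTFFK", strrep("G", 30)),
    P3 = paste0("MK", "VVNGSLLK", strrep("S", 30)))))
  topo <- data.frame(accession = c("P1", "P2"), predictor = "predictor-A",
                     start = 1L, end = 20L, label = "extracellular",
                     stringsAsFactors = FALSE)
  psms <- readPsmTable(writePsmTsv(data.frame(
    spectrum_id = c("S1", "S2", "S3"),
    peptide = c("LLNGSAVK", "TTNGTFFK", "VVNGSLLK"),
    modifications = "3|Deamidated",
    proteins = c("P1", "P2", "P3"), stringsAsFactors = FALSE)))
  cat <- curateCatalog(psms, prot, topo)
  expect_s4_class(cat, "SurfaceCatalog")
  expect_true(validObject(cat))
  expect_equal(nrow(scmTable(cat)), 3L)
  filt <- scmFilteredTable(cat)
  expect_setequal(filt$accession, c("P1", "P2"))
  expect_equal(unique(filt$branch), "cirfess_positive")
  ## subset relation and branch conservation
  expect_true(all(filt$accession %in% scmTable(cat)$accession))
  expect_equal(nrow(filt),
               sum(table(filt$branch)))
  ## specificity numerators bounded by denominators
  sp <- captureSpecificity(cat)
  expect_lte(sp$psm_level$numerator, sp$psm_level$denominator)
  expect_lte(sp$protein_level$numerator, sp$protein_level$denominator)
  ## glycosites recorded at protein coordinates
  gl <- glycositeTable(cat)
  expect_equal(sort(gl$position), c(5L, 5L, 5L))
})

test_that("a catalog with no surface calls has an empty filtered table", {
  prot <- readProteome(writeFasta(c(
    P1 = paste0("MK", "LLNGSAVK", strrep("A", 30)))))
  psms <- readPsmTable(writePsmTsv(data.frame(
    spectrum_id = "S1", peptide = "LLNGSAVK",
    modifications = "3|Deamidated", proteins = "P1",
    stringsAsFactors = FALSE)))
  cat <- curateCatalog(psms, prot)   # no topology, no surface predictions
  expect_equal(nrow(scmTable(cat)), 1L)
  expect_equal(nrow(scmFilteredTable(cat)), 0L)
  expect_named(scmFilteredTable(cat))
})
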