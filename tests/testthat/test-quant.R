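mkMat <- function(values, nrow, runs = NULL) {
  m <- matrix(values, nrow = nrow)
  colnames(m) <- if (is.null(runs)) paste0("r", seq_len(ncol(m))) else runs
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  m
}

test_that("log2 transform preserves missingness and rejects non-positives", {
  m <- mkMat(c(8, NA, 0, 4), 2)
  expect_warning(lg <- log2Transform(m), "non-positive")
  expect_equal(lg[1, 1], 3)
  expect_true(is.na(lg[2, 1]))
  expect_true(is.na(lg[1, 2]))   # the zero
  expect_equal(lg[2, 2], 2)
})

test_that("equalize-median normalization is an exact per-run shift", {
  m <- mkMat(c(9, 10, 11, 11, 12, 13), 3)
  norm <- equalizeMedians(m)
  expect_equal(unname(apply(norm, 2, median)), c(11, 11))
  ## shift-only: within-run differences unchanged
  expect_equal(diff(norm[, 1]), diff(m[, 1]))
  ## single run and already-equal medians are identities
  expect_equal(equalizeMedians(m[, 1, drop = FALSE]), m[, 1, drop = FALSE])
  eq <- mkMat(c(1, 2, 3, 2, 3, 1), 3)
  expect_equal(equalizeMedians(eq), eq)
  withNA <- m; withNA[, 2] <- NA
  expect_error(equalizeMedians(withNA), "no observed")
  set.seed(37)
  for (i in 1:20) {
    x <- mkMat(rnorm(8 * 5, 20, 3), 8)
    n <- equalizeMedians(x)
    target <- median(apply(x, 2, median))
    expect_equal(unname(apply(n, 2, median)), rep(target, 5))
  }
})

test_that("median polish recovers additive structure exactly", {
  expect_equal(unname(medianPolishSummary(mkMat(c(3, 5, 4, 6), 2))), c(4, 5))
  ## single feature: summaries are the feature values
  one <- mkMat(c(7, 8, 9), 1)
  expect_equal(unname(medianPolishSummary(one)), c(7, 8, 9))
  ## permutation of features does not change run summaries
  set.seed(41)
  m <- mkMat(rnorm(6 * 4, 20), 6)
  expect_equal(medianPolishSummary(m), medianPolishSummary(m[sample(6), ]))
  ## additive matrices: summary equals the per-run column median
  for (i in 1:20) {
    r <- rnorm(sample(2:8, 1)); c_ <- rnorm(sample(2:6, 1))
    add <- outer(r, c_, `+`)
    colnames(add) <- paste0("r", seq_along(c_))
    expect_equal(unname(medianPolishSummary(add)),
                 unname(apply(add, 2, median)), tolerance = 1e-6)
  }
  ## missing entries are tolerated
  mna <- mkMat(c(3, 5, 4, 6, NA, 7), 2)
  expect_equal(length(medianPolishSummary(mna)), 3L)
  expect_error(medianPolishSummary(mkMat(rep(NA_real_, 4), 2)),
               "all-missing")
})

test_that("censored imputation respects thresholds and fixed points", {
  ## no missing entries: identity
  full <- mkMat(rnorm(12, 20), 3)
  expect_identical(imputeCensored(full, proteins = rep("P", 3)), full)
  ## an imputed entry never exceeds its feature threshold
  m <- mkMat(c(8.0, 9.1, 8.2, 9.0, NA, 9.2, 7.9, 8.9), 2)
  out <- imputeCensored(m, proteins = rep("P", 2))
  expect_false(anyNA(out))
  expect_lte(out[1, 3], min(m[1, ], na.rm = TRUE))
  ## fewer than two observed values: left alone and flagged
  sparse <- mkMat(c(8, NA, NA, NA), 1)
  out2 <- imputeCensored(sparse, proteins = "P")
  expect_equal(sum(is.na(out2)), 3L)
  expect_equal(attr(out2, "unimputed"), "P")
})

test_that("differential testing matches a direct t-test oracle", {
  m <- rbind(PA = c(8.0, 8.1, 7.9, 10.0, 10.1, 9.9),
             PB = c(5, 5, 5, 5, 5, 5))
  colnames(m) <- paste0("r", 1:6)
  design <- data.frame(run = paste0("r", 1:6),
                       group = rep(c("ctl", "case"), each = 3))
  res <- differentialTest(m, design)
  pa <- res[res$accession == "PA", ]
  ## group1 = first factor level = "case" (alphabetical); fc = ctl - case
  expect_equal(pa$log2fc, -2, tolerance = 1e-9)
  oracle <- t.test(m["PA", 1:3], m["PA", 4:6], var.equal = TRUE)$p.value
  expect_equal(pa$p_value, oracle)
  expect_true(pa$significant)
  pb <- res[res$accession == "PB", ]
  expect_equal(pb$log2fc, 0)
  expect_false(pb$significant)
  ## BH adjustment equals the hand step-up on the computed p-values
  expect_equal(res$adj_p, oracleBH(res$p_value))
  ## ratio-scale thresholding: |log2fc| >= log2(1.5)
  r2 <- differentialTest(matrix(c(8, 8.05, 7.95, 8.8, 8.85, 8.75), 1,
                                dimnames = list("PC", paste0("r", 1:6))),
                         design, fcScale = "ratio")
  expect_true(abs(r2$log2fc) >= log2(1.5))
  expect_error(differentialTest(m, transform(design, group = "one")),
               "two groups")
})

test_that("BH matches the textbook step-up sequence", {
  expect_equal(oracleBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(43)
  p <- runif(200)
  expect_equal(p.adjust(p, "BH"), oracleBH(p))
})

test_that("replicate QC reports %CV on raw scale and Pearson on log2", {
  raw <- mkMat(c(100, 200, 100, 200, 100, 200), 2,
               runs = c("a", "b", "c"))
  qc <- replicateQC(raw, list(set1 = c("a", "b", "c")))
  expect_equal(qc$set1$median_cv_percent, 0)
  expect_equal(unname(qc$set1$median_pearson), 1)
  two <- mkMat(c(90, 110), 1, runs = c("a", "b"))
  qc2 <- replicateQC(two, list(s = c("a", "b")))
  expect_equal(qc2$s$median_cv_percent, 100 * sd(c(90, 110)) / 100,
               tolerance = 1e-6)
  expect_equal(qc2$s$median_cv_percent, 14.14, tolerance = 1e-3)
  expect_warning(replicateQC(raw, list(solo = "a")), "fewer than 2")
})
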