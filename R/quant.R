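#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
#' @importFrom S4Vectors DataFrame
NULL

## Accept a SummarizedExperiment or a bare matrix; apply f to the matrix and
## rewrap. f: matrix -> matrix of identical shape.
.onAssay <- function(x, f) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x) <- f(SummarizedExperiment::assay(x))
    x
  } else f(x)
}

.assayOf <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x) else x
}

#' Read a feature intensity matrix and its run design
#'
#' @param intensityPath TSV with columns `protein`, `feature`, then one
#'   column per run holding raw intensities (empty or `NA` = missing).
#' @param designPath TSV with columns `run`, `group` and optional
#'   `replicate_set`; every run column of the intensity table must appear.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"intensity"` (features x runs), `rowData` columns `protein`/`feature`
#'   and `colData` columns `run`/`group` (and `replicate_set` if given).
#' @export
readIntensityMatrix <- function(intensityPath, designPath) {
  df <- readTsv(intensityPath, required = c("protein", "feature"))
  design <- readTsv(designPath, required = c("run", "group"))
  runs <- setdiff(colnames(df), c("protein", "feature"))
  if (!length(runs)) stop("no run columns in intensity table", call. = FALSE)
  missing <- setdiff(runs, design$run)
  if (length(missing)) {
    stop("run(s) absent from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, runs, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$feature
  design <- design[match(runs, design$run), , drop = FALSE]
  cd <- S4Vectors::DataFrame(design, row.names = design$run)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    rowData = S4Vectors::DataFrame(protein = df$protein,
                                   feature = df$feature),
    colData = cd)
}

#' Log2-transform raw intensities
#'
#' Elementwise log2; missing entries stay missing. Zero or negative
#' intensities carry no usable signal and are set missing, with a warning
#' reporting how many.
#'
#' @param x `SummarizedExperiment` or numeric matrix of raw intensities.
#' @return Same container, log2 scale.
#' @export
log2Transform <- function(x) {
  .onAssay(x, function(m) {
    bad <- !is.na(m) & m <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive intensit",
              if (sum(bad) == 1L) "y" else "ies", " set to missing",
              call. = FALSE)
      m[bad] <- NA_real_
    }
    log2(m)
  })
}

#' Equalize-median normalization
#'
#' Shifts each run (column) so all run medians equal the median of the
#' original run medians. A pure per-column shift: within-run differences
#' between features are untouched. Operates on log2 intensities.
#'
#' @param x `SummarizedExperiment` or matrix of log2 intensities.
#' @return Same container, normalized.
#' @export
equalizeMedians <- function(x) {
  .onAssay(x, function(m) {
    med <- apply(m, 2L, stats::median, na.rm = TRUE)
    if (any(is.na(med))) {
      stop("run(s) with no observed values: ",
           paste(colnames(m)[is.na(med)], collapse = ", "), call. = FALSE)
    }
    sweep(m, 2L, med - stats::median(med))
  })
}

#' Tukey median-polish summary of one protein block
#'
#' Iterative row/column median sweeping (tolerance 1e-6, at most 100
#' iterations); the run-level summary is the overall effect plus the column
#' effect. Missing entries are ignored in the medians. Even-length medians
#' use the midpoint convention throughout.
#'
#' @param block Numeric matrix, features x runs, log2 scale.
#' @return Numeric vector of run-level summaries (one per column; `NA` for a
#'   run with no observed feature).
#' @export
medianPolishSummary <- function(block) {
  block <- as.matrix(block)
  if (all(is.na(block))) stop("all-missing block", call. = FALSE)
  if (nrow(block) == 1L) return(block[1L, ])
  mp <- stats::medpolish(block, eps = 1e-6, maxiter = 100L, na.rm = TRUE,
                         trace.iter = FALSE)
  out <- mp$overall + mp$col
  out[colSums(!is.na(block)) == 0L] <- NA_real_
  names(out) <- colnames(block)
  out
}

#' Summarize feature-level intensities to protein run-level values
#'
#' Applies [medianPolishSummary()] to each protein's feature x run block.
#'
#' @param x Feature-level `SummarizedExperiment` (log2 scale) with a
#'   `protein` rowData column, or a matrix plus `proteins` vector.
#' @param proteins Row-aligned protein ids (required for matrix input).
#' @return Protein x run container of log2 run summaries: a
#'   `SummarizedExperiment` (assay `"log2summary"`) for SE input, else a
#'   matrix.
#' @export
summarizeRuns <- function(x, proteins = NULL) {
  m <- .assayOf(x)
  if (is(x, "SummarizedExperiment")) {
    proteins <- SummarizedExperiment::rowData(x)$protein
  }
  if (is.null(proteins)) stop("protein ids required", call. = FALSE)
  prots <- unique(proteins)
  out <- t(vapply(prots, function(p) {
    medianPolishSummary(m[proteins == p, , drop = FALSE])
  }, numeric(ncol(m))))
  dimnames(out) <- list(prots, colnames(m))
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::SummarizedExperiment(
      assays = list(log2summary = out),
      colData = SummarizedExperiment::colData(x))
  } else out
}

## Fit a gaussian AFT model with left-censoring on one protein block and
## return predictions for the censored cells. Falls back to simpler model
## formulas when the full feature+run fit is inestimable.
.aftImputeBlock <- function(block, thresholds) {
  idx <- which(!is.na(block) | is.na(block), arr.ind = TRUE)  # all cells
  obs <- !is.na(block[idx])
  y <- ifelse(obs, block[idx], thresholds[idx[, 1L]])
  keep <- !is.na(y)                      # censored cell in an all-NA row
  d <- data.frame(y = y[keep], event = as.integer(obs[keep]),
                  feature = factor(rownames(block)[idx[keep, 1L]]),
                  run = factor(colnames(block)[idx[keep, 2L]]))
  ## a run with no observed value in the block gives the AFT model an
  ## unbounded-below run coefficient (only censored terms constrain it);
  ## drop the run covariate in that case -- there is no information about
  ## that run's effect and the threshold truncation bounds the imputation
  runObs <- tapply(d$event, d$run, sum)
  useRun <- all(runObs > 0L)
  forms <- if (useRun) {
    list(y ~ feature + run, y ~ feature, y ~ run, y ~ 1)
  } else {
    list(y ~ feature, y ~ 1)
  }
  if (nlevels(d$feature) < 2L) {
    forms <- if (useRun) list(y ~ run, y ~ 1) else list(y ~ 1)
  }
  fit <- NULL
  for (f in forms) {
    fit <- tryCatch(
      suppressWarnings(survival::survreg(
        stats::as.formula(paste0("survival::Surv(y, event, type = \"left\")",
                                 " ~ ", deparse(f[[3L]]))),
        data = d, dist = "gaussian")),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) break
    fit <- NULL
  }
  cens <- idx[keep, , drop = FALSE][d$event == 0L, , drop = FALSE]
  if (!nrow(cens)) return(block)
  pred <- if (is.null(fit)) rep(mean(d$y[d$event == 1L]), nrow(cens)) else
    stats::predict(fit, newdata = d[d$event == 0L, , drop = FALSE],
                   type = "response")
  ## truncate at the censoring threshold: an imputed value never exceeds it
  block[cens] <- pmin(pred, thresholds[cens[, 1L]])
  block
}

#' Impute left-censored missing intensities (AFT model)
#'
#' Intensities missing because they fell below the detection limit are
#' left-censored, not missing at random; replacing them requires a model
#' that respects the censoring. Per protein, a gaussian accelerated failure
#' time regression on the log2 scale (feature and run covariates) is fitted
#' treating each missing entry as left-censored at its feature's censoring
#' threshold -- by default the minimum observed value of that feature.
#' Censored entries are replaced by model predictions truncated at the
#' threshold, so an imputed value never exceeds what censoring allows.
#'
#' @param x Feature-level `SummarizedExperiment` (log2 scale, normalized)
#'   with a `protein` rowData column, or a matrix plus `proteins`.
#' @param proteins Row-aligned protein ids (matrix input).
#' @param thresholdFun Function mapping a feature's observed values to its
#'   censoring threshold; default `min`.
#' @return Same container with censored entries filled. Proteins with fewer
#'   than 2 observed values are left unimputed and listed in the
#'   `"unimputed"` attribute (or metadata column for SE input). A matrix
#'   with no missing entries is returned unchanged.
#' @export
imputeCensored <- function(x, proteins = NULL, thresholdFun = min) {
  m <- .assayOf(x)
  if (is(x, "SummarizedExperiment")) {
    proteins <- SummarizedExperiment::rowData(x)$protein
  }
  if (is.null(proteins)) stop("protein ids required", call. = FALSE)
  if (!anyNA(m)) return(x)
  unimputed <- character()
  for (p in unique(proteins)) {
    rows <- which(proteins == p)
    block <- m[rows, , drop = FALSE]
    if (!anyNA(block)) next
    if (sum(!is.na(block)) < 2L) {
      unimputed <- c(unimputed, p)
      next
    }
    if (is.null(rownames(block))) rownames(block) <- as.character(rows)
    rownames(block) <- make.unique(rownames(block))
    thresholds <- apply(block, 1L, function(r)
      if (all(is.na(r))) NA_real_ else thresholdFun(r[!is.na(r)]))
    m[rows, ] <- .aftImputeBlock(block, thresholds)
  }
  out <- .onAssay(x, function(old) m)
  if (is(out, "SummarizedExperiment")) {
    S4Vectors::metadata(out)$unimputed <- unimputed
  } else {
    attr(out, "unimputed") <- unimputed
  }
  out
}

#' Two-group differential abundance test
#'
#' Equal-variance two-sample t-test on protein run-level log2 summaries,
#' with Benjamini-Hochberg adjustment across all tested proteins. The log2
#' fold change is `mean(group2) - mean(group1)` where `group1` is the first
#' level of the design's group factor (set the factor levels to choose the
#' reference). A protein is flagged significant when `|log2fc| >=
#' fcThreshold` and adjusted p `< alpha`; with `fcScale = "ratio"` the
#' threshold is applied to the raw fold change `2^log2fc` instead.
#'
#' @param x Protein x run `SummarizedExperiment` (assay `"log2summary"`) or
#'   matrix.
#' @param design `data.frame` with `run`, `group` (exactly two groups);
#'   taken from `colData` for SE input.
#' @param fcThreshold Fold-change threshold (default 1.5, log2 scale).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fcScale `"log2"` (default) or `"ratio"`.
#' @return `data.frame`: `accession`, `log2fc`, `p_value`, `adj_p`,
#'   `significant`.
#' @export
differentialTest <- function(x, design = NULL, fcThreshold = 1.5,
                             alpha = 0.05, fcScale = c("log2", "ratio")) {
  fcScale <- match.arg(fcScale)
  m <- .assayOf(x)
  if (is(x, "SummarizedExperiment")) {
    design <- as.data.frame(SummarizedExperiment::colData(x))
  }
  if (is.null(design)) stop("design required", call. = FALSE)
  grp <- factor(design$group[match(colnames(m), design$run)])
  if (nlevels(grp) != 2L) {
    stop("exactly two groups required, got ", nlevels(grp), call. = FALSE)
  }
  if (any(table(grp) == 0L)) stop("a group has no runs", call. = FALSE)
  g1 <- levels(grp)[1L]
  res <- t(apply(m, 1L, function(v) {
    a <- v[grp == g1 & !is.na(v)]
    b <- v[grp != g1 & !is.na(v)]
    fc <- mean(b) - mean(a)
    p <- if (length(a) >= 2L && length(b) >= 2L) {
      if (stats::var(a) + stats::var(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        stats::t.test(b, a, var.equal = TRUE)$p.value
      }
    } else NA_real_
    c(fc, p)
  }))
  out <- data.frame(accession = rownames(m), log2fc = res[, 1L],
                    p_value = res[, 2L], stringsAsFactors = FALSE)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  cut <- if (fcScale == "log2") fcThreshold else log2(fcThreshold)
  out$significant <- !is.na(out$adj_p) & abs(out$log2fc) >= cut &
    out$adj_p < alpha
  rownames(out) <- NULL
  out
}

#' Replicate quality control: %CV and Pearson correlation
#'
#' Per replicate set: the per-feature percent coefficient of variation
#' (100 x sd/mean) computed on RAW intensities and summarized as the median
#' over features, plus all pairwise Pearson correlations of log2 intensities
#' between replicate runs.
#'
#' @param raw Numeric matrix of raw intensities, features x runs.
#' @param replicateSets Named list: set name -> character vector of run
#'   (column) names. Sets of size 1 are skipped with a warning.
#' @return List per set: `median_cv_percent`, `pearson` (named vector of
#'   pairwise correlations), `median_pearson`.
#' @export
replicateQC <- function(raw, replicateSets) {
  out <- list()
  for (nm in names(replicateSets)) {
    runs <- replicateSets[[nm]]
    if (length(runs) < 2L) {
      warning("replicate set '", nm, "' has fewer than 2 runs; skipped",
              call. = FALSE)
      next
    }
    sub <- raw[, runs, drop = FALSE]
    cv <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L || mean(v) == 0) return(NA_real_)
      100 * stats::sd(v) / mean(v)
    })
    lg <- log2(sub)
    pairs <- utils::combn(runs, 2L)
    r <- apply(pairs, 2L, function(p)
      stats::cor(lg[, p[1L]], lg[, p[2L]], use = "pairwise.complete.obs"))
    names(r) <- apply(pairs, 2L, paste, collapse = "~")
    out[[nm]] <- list(median_cv_percent = stats::median(cv, na.rm = TRUE),
                      pearson = r,
                      median_pearson = stats::median(r, na.rm = TRUE))
  }
  out
}

#' Run the full label-free quantification workflow
#'
#' log2 transform, equalize-median normalization, censored imputation,
#' median-polish summarization and two-group differential testing, in that
#' order.
#'
#' @param se Feature-level raw-intensity `SummarizedExperiment` from
#'   [readIntensityMatrix()].
#' @param impute Run [imputeCensored()] (default `TRUE`).
#' @param fcThreshold,alpha,fcScale Passed to [differentialTest()].
#' @return List: `summaries` (protein x run SE), `results`
#'   (differential `data.frame`).
#' @export
quantWorkflow <- function(se, impute = TRUE, fcThreshold = 1.5, alpha = 0.05,
                          fcScale = c("log2", "ratio")) {
  fcScale <- match.arg(fcScale)
  x <- equalizeMedians(log2Transform(se))
  if (impute) x <- imputeCensored(x)
  summ <- summarizeRuns(x)
  res <- differentialTest(summ, fcThreshold = fcThreshold, alpha = alpha,
                          fcScale = fcScale)
  list(summaries = summ, results = res)
}
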