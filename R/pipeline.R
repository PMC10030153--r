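## Known configuration keys, their defaults, and whether they are paths.
.CONFIG_SCHEMA <- list(
  fasta = list(default = NULL, path = TRUE, required = TRUE),
  topology = list(default = NULL, path = TRUE),
  surface_predictions = list(default = NULL, path = TRUE),
  psm = list(default = NULL, path = TRUE),
  psm_dialect = list(default = "generic"),
  intensity = list(default = NULL, path = TRUE),
  design = list(default = NULL, path = TRUE),
  abundance = list(default = NULL, path = TRUE),
  identifications = list(default = NULL, path = TRUE),
  include_nxc = list(default = FALSE),
  missed_cleavages = list(default = 0L),
  sp_rule = list(default = "any"),
  marker_mode = list(default = "omni"),
  fc_threshold = list(default = 1.5),
  fc_scale = list(default = "log2"),
  alpha = list(default = 0.05),
  min_experiments = list(default = 1L),
  impute = list(default = TRUE),
  seed = list(default = 1L),
  out_dir = list(default = "glycoCSC_out"))

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, rejects unknown keys by name, fills defaults
#' (fold-change threshold 1.5 on the log2 scale and adjusted-p cutoff 0.05,
#' the significance defaults used throughout), and checks threshold ranges.
#' The effective configuration is echoed alongside the outputs by
#' [runPipeline()] and revalidates to itself.
#'
#' @param path YAML file; keys as in the schema (see Details), all optional
#'   except `fasta`.
#' @return Named list: the effective configuration.
#' @details Recognized keys: input paths `fasta` (required), `topology`,
#'   `surface_predictions`, `psm`, `intensity`, `design`, `abundance`,
#'   `identifications`; options `psm_dialect` (`generic`/`pd`),
#'   `include_nxc`, `missed_cleavages` (0-2), `sp_rule` (`any`/`majority`),
#'   `marker_mode` (`omni`/`genie`), `fc_threshold`, `fc_scale`
#'   (`log2`/`ratio`), `alpha`, `min_experiments`, `impute`, `seed`,
#'   `out_dir`.
#' @export
validateConfig <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.CONFIG_SCHEMA))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- lapply(names(.CONFIG_SCHEMA), function(k) {
    if (!is.null(raw[[k]])) raw[[k]] else .CONFIG_SCHEMA[[k]]$default
  })
  names(cfg) <- names(.CONFIG_SCHEMA)
  for (k in names(.CONFIG_SCHEMA)) {
    s <- .CONFIG_SCHEMA[[k]]
    if (isTRUE(s$required) && is.null(cfg[[k]])) {
      stop("missing required configuration key: ", k, call. = FALSE)
    }
  }
  if (!cfg$psm_dialect %in% c("generic", "pd")) {
    stop("psm_dialect must be 'generic' or 'pd'", call. = FALSE)
  }
  if (!cfg$sp_rule %in% c("any", "majority")) {
    stop("sp_rule must be 'any' or 'majority'", call. = FALSE)
  }
  if (!cfg$marker_mode %in% c("omni", "genie")) {
    stop("marker_mode must be 'omni' or 'genie'", call. = FALSE)
  }
  if (!cfg$fc_scale %in% c("log2", "ratio")) {
    stop("fc_scale must be 'log2' or 'ratio'", call. = FALSE)
  }
  if (cfg$missed_cleavages < 0L || cfg$missed_cleavages > 2L) {
    stop("missed_cleavages must be in 0..2", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)",
                                             call. = FALSE)
  if (cfg$fc_threshold < 0) stop("fc_threshold must be >= 0", call. = FALSE)
  if (cfg$min_experiments < 1L) stop("min_experiments must be >= 1",
                                     call. = FALSE)
  cfg
}

#' Run the end-to-end curation and quantification pipeline
#'
#' Orchestrates detectability scoring, PSM curation and classification,
#' orientation inference, marker prioritization, quantification and set
#' comparison over the inputs named in the configuration, writing one TSV or
#' JSON per product into `out_dir`. Stages whose inputs are absent from the
#' configuration are skipped. Output is deterministic given inputs and seed;
#' every table carries a provenance header with the package version and the
#' configuration hash. On any stage failure the partial outputs are removed
#' and an error naming the stage is raised.
#'
#' @param config Path to a YAML configuration, or a list already validated
#'   by [validateConfig()].
#' @return Invisibly, a list of the written paths plus the in-memory
#'   products (`cirfess`, `catalog`, `classification`, ...).
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- objectHash(cfg[setdiff(names(cfg), "out_dir")])
  prov <- c(config_hash = hash)
  written <- character()
  log <- character()
  products <- list()
  note <- function(...) log <<- c(log, paste0(...))
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    writeTsv(df, p, provenance = prov)
    written <<- c(written, p)
    note("wrote ", name, " (", nrow(df), " rows)")
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(cfg$seed)

  ## --- inputs ---------------------------------------------------------
  proteins <- stage("read-proteome", readProteome(cfg$fasta))
  topology <- if (!is.null(cfg$topology)) {
    stage("read-topology", readTopology(cfg$topology, proteins))
  } else NULL
  surfacePred <- if (!is.null(cfg$surface_predictions)) {
    stage("read-surface-predictions",
          readSurfacePredictions(cfg$surface_predictions, proteins))
  } else NULL

  ## --- digest-score ---------------------------------------------------
  cirfess <- stage("digest-score",
                   cirfessScore(proteins, topology, surfacePred,
                                missedCleavages = cfg$missed_cleavages,
                                includeNxc = cfg$include_nxc,
                                spRule = cfg$sp_rule))
  products$cirfess <- cirfess
  emit(cirfessScores(cirfess), "cirfess_scores.tsv")
  emit(contributingPeptides(cirfess), "cirfess_peptides.tsv")

  ## --- database-level classification ----------------------------------
  stage("classify", {
    cs <- cirfessScores(cirfess)
    spc <- rep(0L, length(proteins))
    spFlag <- rep(FALSE, length(proteins))
    names(spc) <- names(spFlag) <- names(proteins)
    if (!is.null(surfacePred)) {
      spc[surfacePred$accession] <- surfacePred$spc_score
      spFlag[surfacePred$accession] <- signalPeptideCall(surfacePred,
                                                         cfg$sp_rule)
    }
    cls <- cbind(
      data.frame(accession = names(proteins),
                 cirfess_score = cs$score[match(names(proteins),
                                                cs$accession)],
                 spc_score = unname(spc), signal_peptide = unname(spFlag),
                 stringsAsFactors = FALSE),
      classifySurface(cs$score[match(names(proteins), cs$accession)],
                      unname(spc), unname(spFlag)))
    products$classification <- cls
    emit(cls, "classification.tsv")
  })

  ## --- curate ---------------------------------------------------------
  if (!is.null(cfg$psm)) {
    stage("curate", {
      psms <- readPsmTable(cfg$psm, dialect = cfg$psm_dialect)
      catalog <- curateCatalog(psms, proteins, topology, surfacePred,
                               cirfess = cirfess,
                               includeNxc = cfg$include_nxc,
                               missedCleavages = cfg$missed_cleavages,
                               spRule = cfg$sp_rule)
      products$catalog <- catalog
      emit(scmTable(catalog), "scm.tsv")
      emit(scmFilteredTable(catalog), "scm_filtered.tsv")
      emit(glycositeTable(catalog), "glycosites.tsv")
      sp <- file.path(outDir, "specificity.json")
      jsonlite::write_json(captureSpecificity(catalog), sp,
                           auto_unbox = TRUE, digits = NA)
      written <- c(written, sp)
      note("wrote specificity.json")

      ## orientation from glycosite parity, for proteins with TM topology
      if (!is.null(topology)) {
        gl <- glycositeTable(catalog)
        orient <- do.call(rbind, lapply(unique(gl$accession), function(a) {
          tm <- topology[topology$accession == a &
                           topology$label == "transmembrane", , drop = FALSE]
          if (!nrow(tm)) return(NULL)
          v <- inferOrientation(gl$position[gl$accession == a], tm)
          data.frame(accession = a, orientation = v$orientation,
                     status = v$status,
                     n_sites = sum(gl$accession == a),
                     n_excluded = length(v$excluded_sites),
                     stringsAsFactors = FALSE)
        }))
        if (!is.null(orient)) emit(orient, "orientation.tsv")
      }
    })
  }

  ## --- prioritize -----------------------------------------------------
  if (!is.null(cfg$abundance)) {
    stage("prioritize", {
      ab <- readTsv(cfg$abundance, required = "accession")
      m <- as.matrix(ab[, setdiff(colnames(ab), "accession"), drop = FALSE])
      rownames(m) <- ab$accession
      spc <- NULL
      if (!is.null(surfacePred)) {
        spc <- stats::setNames(surfacePred$spc_score, surfacePred$accession)
      }
      rk <- rankMarkers(m, spc = spc, mode = cfg$marker_mode)
      products$markers <- rk
      emit(rk, "markers.tsv")
    })
  }

  ## --- quant ----------------------------------------------------------
  if (!is.null(cfg$intensity) && !is.null(cfg$design)) {
    stage("quant", {
      se <- readIntensityMatrix(cfg$intensity, cfg$design)
      qw <- quantWorkflow(se, impute = cfg$impute,
                          fcThreshold = cfg$fc_threshold, alpha = cfg$alpha,
                          fcScale = cfg$fc_scale)
      products$quant <- qw
      summ <- SummarizedExperiment::assay(qw$summaries)
      emit(cbind(data.frame(accession = rownames(summ),
                            stringsAsFactors = FALSE),
                 as.data.frame(summ)), "run_summaries.tsv")
      res <- qw$results
      res$neg_log10_adj_p <- -log10(res$adj_p)
      emit(res, "differential.tsv")
    })
  }

  ## --- compare --------------------------------------------------------
  if (!is.null(cfg$identifications)) {
    stage("compare", {
      ids <- readTsv(cfg$identifications,
                     required = c("accession", "dataset", "experiment"))
      pm <- buildPresence(ids, minExperiments = cfg$min_experiments)
      ix <- exclusiveIntersections(pm)
      ix$accessions <- vapply(ix$accessions, paste, character(1),
                              collapse = ";")
      products$intersections <- ix
      emit(ix, "intersections.tsv")
    })
  }

  ## --- effective config + log -----------------------------------------
  cfgPath <- file.path(outDir, "effective_config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  writeLines(c(sprintf("# glycoCSC pipeline, config %s", hash), log),
             file.path(outDir, "run.log"))
  invisible(c(list(out_dir = outDir, files = written, config = cfg,
                   log = log), products))
}
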