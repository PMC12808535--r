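.configDefaults <- function() list(
  counts = NULL, genes = NULL, cells = NULL, metadata = NULL,
  signatures = NULL, orientation = "genes_by_cells",
  driver = NULL, target = NULL, g1s = "G1S", g2m = "G2M",
  scale_factor = 1e4,
  tail_fraction = 0.10, min_cells_per_bin = 20L, variance_floor = 1e-8,
  n_bins = 24L, n_ctrl = 100L,
  null_reps = 1000L, null_bins = 25L,
  level = 0.95, log_library = TRUE, floor_q = FALSE, df_correction = TRUE,
  spearman = FALSE, seed = 1L, overwrite = FALSE)

.configRequired <- c("driver", "target")

#' Load and validate a pipeline configuration
#'
#' Reads a YAML key-value file (or takes a named list), rejects unknown
#' keys (no silent typo tolerance), checks required keys, and
#' materializes every default explicitly so the returned object is a
#' complete record of the run.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return complete config list of class `runConfig`.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- defaults
  out[names(config)] <- config
  missing <- .configRequired[vapply(out[.configRequired], is.null, logical(1))]
  if (length(missing))
    stop("missing required configuration key(s): ",
         paste(missing, collapse = ", "))
  stopifnot(out$tail_fraction > 0, out$tail_fraction <= 0.5,
            out$min_cells_per_bin >= 2, out$level > 0, out$level < 1,
            out$scale_factor > 0)
  structure(out, class = "runConfig")
}

# serialize a MetaResult for the report
.metaAsList <- function(m) {
  out <- list(effect = m@effect, tau2 = m@tau2, Q = m@Q, k = m@k,
              se_hk = m@se, ci = m@ci, t = m@tstat, p = m@p,
              level = m@level,
              excluded = if (nrow(m@excluded)) m@excluded else list())
  if (is(m, "CorMetaResult")) { out$r <- m@rEffect; out$r_ci <- m@rCI }
  out
}

#' Run the full contrast / meta-analysis / specificity pipeline
#'
#' Load -> normalize -> score (target signatures + cell-cycle
#' covariates) -> per-patient tail stratification -> tail contrasts ->
#' DL+HK meta-analysis -> covariate-adjusted Fisher-z
#' partial-correlation meta-analysis -> matched random gene-set
#' specificity null -> report.  Stage outputs are written as they are
#' produced, so partial results survive a downstream failure; each
#' stage error is rethrown prefixed with the stage name.  When more
#' than one target signature is analyzed, Benjamini-Hochberg adjusted
#' q-values are reported alongside the raw meta-analysis p-values.
#'
#' @param config a [validateConfig()] result, path, or named list.
#' @param cohort optional in-memory `SingleCellExperiment` (skips the
#'   counts/metadata file stage).
#' @param signatureSet optional in-memory [SignatureSet-class] (skips
#'   the GMT stage).
#' @param outDir output directory for TSV/JSON stage outputs; NULL for
#'   in-memory only.  An existing report is not overwritten unless
#'   `overwrite: true` is configured.
#' @return ReportBundle: list with `contrasts` (per-patient, per-target),
#'   `meta` (per-target [MetaResult-class]), `correlationMeta` (per
#'   target), `nulls` (per-target [NullDistribution-class]), `summary`
#'   (data.frame with effect, CI, p, q per target) and `provenance`.
#' @export
runPipeline <- function(config, cohort = NULL, signatureSet = NULL,
                        outDir = NULL) {
  if (!inherits(config, "runConfig")) config <- validateConfig(config)
  if (!is.null(outDir)) {
    if (file.exists(file.path(outDir, "report.json")) && !config$overwrite)
      stop("stage report: ", outDir,
           " already contains a report; set overwrite: true to replace")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  }
  emit <- function(obj, name) {
    if (is.null(outDir)) return(invisible(NULL))
    write.table(obj, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  x <- stage("load", {
    if (is.null(cohort)) {
      x <- readCounts(config$counts, config$genes, config$cells,
                      orientation = config$orientation)
      attachCellMeta(x, config$metadata)
    } else cohort
  })
  sigs <- stage("signatures", {
    if (is.null(signatureSet)) readGMT(config$signatures) else signatureSet
  })
  targets <- config$target
  for (nm in c(targets, config$g1s, config$g2m))
    if (!nm %in% names(sigs)) stop("stage signatures: signature '", nm,
                                   "' not found", call. = FALSE)

  x <- stage("normalize", normalizeCohort(x, config$scale_factor))

  scores <- stage("score", {
    want <- unique(c(targets, config$g1s, config$g2m))
    scoreModules(x, SignatureSet(geneSets(sigs)[want]),
                 nBins = config$n_bins, nCtrl = config$n_ctrl,
                 seed = .streamSeed(config$seed, "scoring"),
                 exclude = config$driver)
  })
  if (!is.null(outDir))
    write.table(data.frame(cell_id = rownames(scores), scores,
                           check.names = FALSE),
                file.path(outDir, "module_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  tails <- stage("stratify", assignTails(x, config$driver,
                                         config$tail_fraction,
                                         config$min_cells_per_bin))
  covars <- stage("covariates", defaultCovariates(
    x, scores[, c(config$g1s, config$g2m), drop = FALSE],
    logLibrary = config$log_library))

  contrasts <- list(); meta <- list(); cormeta <- list(); nulls <- list()
  for (tg in targets) {
    ct <- stage("contrast", patientContrasts(
      x, scores[, tg], config$driver, config$tail_fraction,
      config$min_cells_per_bin, config$variance_floor, tails = tails))
    contrasts[[tg]] <- ct
    emit(ct, paste0("contrasts_", tg, ".tsv"))
    meta[[tg]] <- stage("meta", metaAnalyzeContrasts(
      ct, level = config$level, floorQ = config$floor_q))
    pcs <- stage("partial_correlation", patientPartialCorrelations(
      x, scores[, tg], config$driver, covars,
      method = if (config$spearman) "spearman" else "pearson"))
    emit(pcs, paste0("partial_correlations_", tg, ".tsv"))
    cormeta[[tg]] <- stage("correlation_meta", metaAnalyzeCorrelations(
      pcs, level = config$level, floorQ = config$floor_q,
      dfCorrection = config$df_correction))
    nd <- stage("specificity_null", empiricalSpecificity(
      x, config$driver, SignatureSet(geneSets(sigs)[tg]),
      nReps = config$null_reps, nBins = config$null_bins,
      seed = .streamSeed(config$seed, "nulls"),
      tailFraction = config$tail_fraction,
      minCells = config$min_cells_per_bin,
      varianceFloor = config$variance_floor, level = config$level,
      scoreBins = config$n_bins, scoreCtrl = config$n_ctrl))
    nulls[[tg]] <- nd
    emit(data.frame(rep = seq_along(nd@nullEffects),
                    pooled_effect = nd@nullEffects),
         paste0("null_distribution_", tg, ".tsv"))
  }

  summary <- data.frame(
    target = targets,
    delta = vapply(meta, pooledEffect, numeric(1)),
    ci_low = vapply(meta, function(m) m@ci[1], numeric(1)),
    ci_high = vapply(meta, function(m) m@ci[2], numeric(1)),
    tau2 = vapply(meta, tau2, numeric(1)),
    k = vapply(meta, function(m) m@k, integer(1)),
    p = vapply(meta, metaP, numeric(1)),
    partial_r = vapply(cormeta, pooledR, numeric(1)),
    partial_r_p = vapply(cormeta, metaP, numeric(1)),
    specificity_p = vapply(nulls, empiricalP, numeric(1)),
    row.names = NULL)
  summary$q <- p.adjust(summary$p, method = "BH")
  emit(summary, "summary.tsv")

  nPatients <- length(tails)
  report <- list(
    summary = summary,
    meta = lapply(meta, .metaAsList),
    correlation_meta = lapply(cormeta, .metaAsList),
    specificity = lapply(nulls, function(nd) list(
      observed = nd@observed, n_reps = nd@nReps,
      n_successful = length(nd@nullEffects), empirical_p = nd@empiricalP)),
    provenance = list(
      config = unclass(config), seed = config$seed,
      n_patients_input = nPatients,
      n_patients_eligible = sum(vapply(tails, `[[`, logical(1), "eligible")),
      package_version = as.character(utils::packageVersion("scContrastMeta"))))
  if (!is.null(outDir))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(report, list(contrasts = contrasts, metaObjects = meta,
                           correlationObjects = cormeta,
                           nullObjects = nulls)))
}
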