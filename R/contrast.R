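#' Stratify one patient's cells into driver-expression tails
#'
#' Cells are sorted by driver expression (ties broken by cell identifier
#' so the split is deterministic); the low tail is the first
#' `t = floor(q * n)` cells and the high tail the last `t`.  The patient
#' is eligible only when `t >= minCells`, mirroring a
#' "10% tails; >= m cells per bin" rule as a floor-based check.
#'
#' @param expr named numeric vector: driver expression for one patient's
#'   cells (names are cell identifiers).
#' @param tailFraction tail fraction q in (0, 0.5] (default 0.10).
#' @param minCells minimum cells per tail m (default 20).
#' @return list with `high`, `low` (cell id vectors), `n`, `eligible`,
#'   `reason` (empty when eligible).
#' @export
stratifyTails <- function(expr, tailFraction = 0.10, minCells = 20L) {
  stopifnot(tailFraction > 0, tailFraction <= 0.5, minCells >= 2L)
  n <- length(expr)
  ids <- names(expr)
  if (is.null(ids) || anyDuplicated(ids))
    stop("expr must be named by unique cell identifiers")
  t <- floor(tailFraction * n)
  if (n < 2L || t < minCells) {
    return(list(high = character(0), low = character(0), n = n,
                eligible = FALSE,
                reason = if (n < 2L) "too few cells"
                         else sprintf("tail size %d < %d", t, minCells)))
  }
  ord <- .orderStable(expr, ids)
  low <- ids[ord[seq_len(t)]]
  high <- ids[ord[seq.int(n - t + 1L, n)]]
  # boundary ties: flag when the tail boundary falls inside a tie run
  bLow <- expr[ids[ord[t]]] == expr[ids[ord[t + 1L]]]
  bHigh <- expr[ids[ord[n - t + 1L]]] == expr[ids[ord[n - t]]]
  if (bLow || bHigh) {
    nTied <- sum(expr %in% expr[c(low[t], high[1L])])
    if (nTied > 0.1 * t)
      .msg(sprintf("tail boundary tie-broken by cell id (%d tied values)", nTied))
  }
  list(high = high, low = low, n = n, eligible = TRUE, reason = "")
}

#' Tail assignments for every patient in a cohort
#'
#' @param x a `SingleCellExperiment` with `logcounts` and a
#'   `patient_id` colData column.
#' @param driver driver gene identifier.
#' @inheritParams stratifyTails
#' @return named list of per-patient assignments (see [stratifyTails()]).
#' @export
assignTails <- function(x, driver, tailFraction = 0.10, minCells = 20L) {
  if (!"patient_id" %in% names(colData(x)))
    stop("cohort lacks a patient_id column; see attachCellMeta()")
  expr <- geneExpression(x, driver)
  pid <- colData(x)$patient_id
  lapply(split(expr, pid), stratifyTails,
         tailFraction = tailFraction, minCells = minCells)
}

#' Per-patient tail contrast of a module score
#'
#' Computes `delta = mean(score | high tail) - mean(score | low tail)`
#' with the Welch sampling variance
#' `v = s2_high / n_high + s2_low / n_low` (sample variances, n-1
#' denominator), floored at `varianceFloor` to prevent infinite
#' meta-analysis weights when a tail is constant.
#'
#' @param scores named numeric vector of per-cell module scores.
#' @param assignment one eligible element of [assignTails()].
#' @param varianceFloor variance floor (default 1e-8).
#' @return one-row data.frame: `delta`, `variance`, `n_high`, `n_low`,
#'   `mean_high`, `mean_low`, `var_high`, `var_low`.
#' @export
computeDelta <- function(scores, assignment, varianceFloor = 1e-8) {
  if (!isTRUE(assignment$eligible))
    stop("computeDelta called on an ineligible patient (",
         assignment$reason, ")")
  hi <- scores[assignment$high]
  lo <- scores[assignment$low]
  if (anyNA(hi) || anyNA(lo)) stop("scores missing for some tail cells")
  vh <- var(hi); vl <- var(lo)
  data.frame(delta = mean(hi) - mean(lo),
             variance = max(vh / length(hi) + vl / length(lo), varianceFloor),
             n_high = length(hi), n_low = length(lo),
             mean_high = mean(hi), mean_low = mean(lo),
             var_high = vh, var_low = vl)
}

#' Per-patient contrast table for a whole cohort
#'
#' Applies [stratifyTails()] and [computeDelta()] per patient and
#' returns the forest-plot-ready table consumed by
#' [metaAnalyzeContrasts()].
#'
#' @param x a `SingleCellExperiment` with `logcounts` and `patient_id`.
#' @param scores named numeric vector of per-cell module scores (one
#'   column of [scoreModules()]).
#' @param driver driver gene identifier.
#' @param tails optional precomputed [assignTails()] result (reused by
#'   the specificity null so the stratification is shared).
#' @inheritParams stratifyTails
#' @inheritParams computeDelta
#' @return data.frame with one row per patient: `patient_id`, `n`,
#'   `eligible`, `reason`, and for eligible patients the
#'   [computeDelta()] columns.
#' @export
patientContrasts <- function(x, scores, driver, tailFraction = 0.10,
                             minCells = 20L, varianceFloor = 1e-8,
                             tails = NULL) {
  if (is.null(tails))
    tails <- assignTails(x, driver, tailFraction, minCells)
  byPatient <- split(scores[colnames(x)], colData(x)$patient_id)
  rows <- lapply(names(tails), function(p) {
    a <- tails[[p]]
    base <- data.frame(patient_id = p, n = a$n, eligible = a$eligible,
                       reason = a$reason)
    if (a$eligible) cbind(base, computeDelta(byPatient[[p]], a, varianceFloor))
    else cbind(base, data.frame(delta = NA_real_, variance = NA_real_,
                                n_high = NA_integer_, n_low = NA_integer_,
                                mean_high = NA_real_, mean_low = NA_real_,
                                var_high = NA_real_, var_low = NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partial correlation after least-squares residualization
#'
#' Residualizes both variables on an intercept plus the covariates by
#' least squares and returns the Pearson correlation of the residuals
#' (or Spearman, computed on rank-transformed residualized inputs).
#' With no covariates this equals the plain correlation.
#'
#' @param a,b numeric vectors.
#' @param covariates numeric matrix (n x c) or NULL.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `z = atanh(r)` (|r| clipped at 1 - 1e-12
#'   before the transform), `n`, `c`.
#' @export
partialCorrelation <- function(a, b, covariates = NULL,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  if (method == "spearman") { a <- rank(a); b <- rank(b) }
  n <- length(a)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    cc <- 0L
    r <- cor(a, b)
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(1, covariates)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("covariate matrix is rank-deficient")
    cc <- ncol(covariates)
    r <- cor(qr.resid(qrX, a), qr.resid(qrX, b))
  }
  rc <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  list(r = r, z = atanh(rc), n = n, c = cc)
}

#' Per-patient covariate-adjusted partial correlations
#'
#' For each patient, the partial correlation between driver expression
#' and module score, adjusted for the supplied covariates (typically
#' log library size and the G1/S / G2/M cell-cycle scores).  Patients
#' with fewer than `minN` cells or rank-deficient covariates are skipped
#' with a logged reason.
#'
#' @param x a `SingleCellExperiment` with `logcounts` and `patient_id`.
#' @param scores named numeric vector of per-cell module scores.
#' @param driver driver gene identifier.
#' @param covariates numeric matrix (cells x c, rownames = cell ids) or
#'   NULL for unadjusted correlations.
#' @param minN minimum cells per patient (default `c + 10`).
#' @param method correlation flavor, see [partialCorrelation()].
#' @return data.frame: `patient_id`, `r`, `z`, `n`, `c`.
#' @export
patientPartialCorrelations <- function(x, scores, driver, covariates = NULL,
                                       minN = NULL,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- geneExpression(x, driver)
  pid <- colData(x)$patient_id
  cc <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (is.null(minN)) minN <- cc + 10L
  rows <- list()
  for (p in unique(pid)) {
    cells <- colnames(x)[pid == p]
    if (length(cells) < minN) {
      .msg("patient ", p, " skipped: ", length(cells), " cells < ", minN)
      next
    }
    Z <- if (is.null(covariates)) NULL
         else as.matrix(covariates)[cells, , drop = FALSE]
    pc <- tryCatch(
      partialCorrelation(expr[cells], scores[cells], Z, method = method),
      error = function(e) { .msg("patient ", p, " skipped: ",
                                 conditionMessage(e)); NULL })
    if (is.null(pc)) next
    rows[[p]] <- data.frame(patient_id = p, r = pc$r, z = pc$z,
                            n = pc$n, c = pc$c)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default covariate matrix for the partial-correlation analysis
#'
#' Log library size (or raw, via `logLibrary = FALSE`) plus the G1/S and
#' G2/M cell-cycle scores.
#'
#' @param x a `SingleCellExperiment` with `library_size` colData.
#' @param cellCycle cells x 2 matrix from [scoreCellCycle()], or NULL.
#' @param logLibrary use log library size (default TRUE).
#' @return numeric matrix with rownames = cell ids.
#' @export
defaultCovariates <- function(x, cellCycle = NULL, logLibrary = TRUE) {
  lib <- colData(x)$library_size
  m <- cbind(library_size = if (logLibrary) log(lib) else lib)
  rownames(m) <- colnames(x)
  if (!is.null(cellCycle)) m <- cbind(m, cellCycle[colnames(x), , drop = FALSE])
  m
}
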