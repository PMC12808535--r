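#' Abundance bins for null-set matching
#'
#' Equal-frequency bins of genes on mean log-normalized expression, with
#' deterministic tie-breaks by gene identifier.  This is the matching
#' criterion behind the size/abundance-matched random gene-set null.
#'
#' @param x a `SingleCellExperiment` with `logcounts`.
#' @param nBins number of bins (default 25; must not exceed the gene
#'   count).
#' @return named integer vector: bin index per gene.
#' @export
binGenesByAbundance <- function(x, nBins = 25L) {
  means <- setNames(as.numeric(Matrix::rowMeans(logcounts(x))), rownames(x))
  .abundanceBins(means, nBins)
}

#' Draw one size/abundance-matched random gene set
#'
#' For each target gene, one gene is drawn uniformly from the target
#' gene's abundance bin, excluding `exclude` and genes already drawn
#' (with replacement once a bin is exhausted, logged; a bin containing
#' only excluded genes falls back to the nearest non-empty bin, logged).
#' Replicates are stream-seeded: replicate `repIndex` is reproducible on
#' its own.
#'
#' @param target character vector: the target signature's genes.
#' @param bins gene-to-bin map from [binGenesByAbundance()].
#' @param exclude genes never drawn (at least the target signature).
#' @param seed root seed of the null stream.
#' @param repIndex replicate index (>= 1).
#' @return character vector, same length as `target`.
#' @export
sampleMatchedSet <- function(target, bins, exclude = target, seed = 0L,
                             repIndex = 1L) {
  if (!all(target %in% names(bins)))
    stop("target gene(s) without an abundance bin: ",
         paste(head(setdiff(target, names(bins)), 5L), collapse = ", "))
  .withSeed(.streamSeed(seed, "nullsets", repIndex), {
    drawn <- character(0)
    genes <- names(bins)
    for (g in target) {
      b <- bins[[g]]
      pool <- genes[bins == b & !(genes %in% exclude) & !(genes %in% drawn)]
      if (length(pool) == 0L) {
        poolAll <- genes[!(genes %in% exclude) & !(genes %in% drawn)]
        if (length(poolAll) == 0L) {
          .msg("all bins exhausted; resampling with replacement")
          pool <- genes[bins == b & !(genes %in% exclude)]
        } else {
          b2 <- bins[poolAll][which.min(abs(bins[poolAll] - b))]
          .msg(sprintf("bin %d exhausted for '%s'; nearest non-empty bin %d",
                       b, g, b2))
          pool <- poolAll[bins[poolAll] == b2]
        }
      }
      drawn <- c(drawn, pool[sample.int(length(pool), 1L)])
    }
    drawn
  })
}

#' Specificity of a signature against matched random gene-set nulls
#'
#' Recomputes the pooled tail-contrast effect for `nReps` random gene
#' sets matched to the target signature in size and abundance bin, using
#' the SAME per-patient tail assignments as the observed analysis (the
#' driver, not the signature, defines the tails), and returns the
#' add-one two-sided empirical p-value of the observed pooled effect.
#'
#' @param x a `SingleCellExperiment` with `logcounts` and `patient_id`.
#' @param driver driver gene identifier.
#' @param target a [SignatureSet-class] with one signature, or a
#'   character vector of genes.
#' @param nReps number of matched null sets (default 1000; >= 19).
#' @param nBins abundance bins for matching (default 25).
#' @param exclude extra genes excluded from the null draws (the target
#'   signature and the driver are always excluded).
#' @param seed root seed; control-gene scoring and null-set sampling use
#'   separate streams derived from it.
#' @param tailFraction,minCells,varianceFloor,level see
#'   [patientContrasts()] and [metaAnalyzeContrasts()].
#' @param scoreBins,scoreCtrl module-scoring parameters (see
#'   [scoreModules()]).
#' @param maxFailFraction error if more than this fraction of replicates
#'   fails (default 0.1).
#' @return A [NullDistribution-class].
#' @export
empiricalSpecificity <- function(x, driver, target, nReps = 1000L,
                                 nBins = 25L, exclude = character(0),
                                 seed = 0L, tailFraction = 0.10,
                                 minCells = 20L, varianceFloor = 1e-8,
                                 level = 0.95, scoreBins = 24L,
                                 scoreCtrl = 100L, maxFailFraction = 0.1) {
  stopifnot(nReps >= 19L)
  if (is(target, "SignatureSet")) {
    stopifnot(length(target) == 1L)
    targetGenes <- target[[1L]]
    targetName <- names(target)[1L]
  } else {
    targetGenes <- as.character(target)
    targetName <- "target"
  }
  targetGenes <- .matchSignature(targetGenes, rownames(x), targetName)
  excludeAll <- unique(c(targetGenes, driver, exclude))
  bins <- binGenesByAbundance(x, nBins)
  tails <- assignTails(x, driver, tailFraction, minCells)

  pooled <- function(sig, scoreSeed) {
    sc <- scoreModules(x, SignatureSet(setNames(list(sig), "s")),
                       nBins = scoreBins, nCtrl = scoreCtrl,
                       seed = scoreSeed, exclude = driver)[, 1L]
    ct <- patientContrasts(x, sc, driver, tailFraction, minCells,
                           varianceFloor, tails = tails)
    pooledEffect(metaAnalyzeContrasts(ct, level = level))
  }

  observed <- pooled(targetGenes, .streamSeed(seed, "score-observed"))
  nullEff <- rep(NA_real_, nReps)
  failures <- list()
  for (r in seq_len(nReps)) {
    res <- tryCatch({
      msig <- sampleMatchedSet(targetGenes, bins, excludeAll, seed, r)
      pooled(msig, .streamSeed(seed, "score-null", r))
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, reason = conditionMessage(res))
    else nullEff[r] <- res
  }
  failed <- if (length(failures)) do.call(rbind, failures)
            else data.frame(rep = integer(0), reason = character(0))
  if (nrow(failed) > maxFailFraction * nReps)
    stop(sprintf("%d of %d null replicates failed (> %.0f%%)",
                 nrow(failed), nReps, 100 * maxFailFraction))
  nullEff <- nullEff[!is.na(nullEff)]
  p <- (1 + sum(abs(nullEff) >= abs(observed))) / (length(nullEff) + 1)
  new("NullDistribution", observed = observed, nullEffects = nullEff,
      empiricalP = p, nReps = as.integer(nReps), failed = failed)
}
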