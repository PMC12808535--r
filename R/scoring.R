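# Equal-frequency abundance bins on mean expression, ties broken by
# gene identifier so the binning is deterministic.
.abundanceBins <- function(means, nBins) {
  n <- length(means)
  if (nBins > n) stop("more bins (", nBins, ") than genes (", n, ")")
  if (nBins < 2L) stop("need >= 2 abundance bins")
  ord <- .orderStable(means, names(means))
  bins <- integer(n)
  bins[ord] <- as.integer(cut(seq_len(n), breaks = nBins))
  names(bins) <- names(means)
  bins
}

# Sample control genes for one signature: nCtrl per signature gene from
# its abundance bin, excluding signature genes (and any extra excluded
# genes, e.g. the contrast driver); with replacement once a bin's pool
# is exhausted; nearest non-empty bin if the pool is empty.  Returns a
# weight vector over genes (weights sum to 1).
.controlWeights <- function(bins, sigGenes, nCtrl, exclude = character(0)) {
  genes <- names(bins)
  w <- numeric(length(genes))
  names(w) <- genes
  eligible <- setdiff(genes, c(sigGenes, exclude))
  poolByBin <- split(eligible, bins[eligible])
  for (g in sigGenes) {
    b <- bins[[g]]
    pool <- poolByBin[[as.character(b)]]
    if (is.null(pool) || length(pool) == 0L) {
      avail <- as.integer(names(poolByBin)[lengths(poolByBin) > 0L])
      b2 <- avail[which.min(abs(avail - b))]
      warning(sprintf(
        "control bin %d exhausted for gene '%s'; using nearest bin %d", b, g, b2))
      pool <- poolByBin[[as.character(b2)]]
    }
    drawn <- if (length(pool) >= nCtrl) sample(pool, nCtrl)
             else sample(pool, nCtrl, replace = TRUE)
    tb <- table(drawn)
    w[names(tb)] <- w[names(tb)] + as.integer(tb)
  }
  w / sum(w)
}

#' Control-gene-adjusted module scores per cell
#'
#' For each signature, genes are ranked by mean log-normalized expression
#' across cells and cut into `nBins` equal-frequency abundance bins; for
#' each signature gene, `nCtrl` control genes are drawn from its bin
#' (excluding signature genes; with replacement once the bin is
#' exhausted).  The score of a cell is the mean expression of the
#' signature genes minus the mean expression of the sampled control
#' genes, so a structureless matrix scores near zero and adding a
#' constant to every entry leaves scores unchanged.  Draws are
#' deterministic given `seed`, with an independent stream per signature.
#'
#' @param x a `SingleCellExperiment` with `logcounts` (see
#'   [normalizeCohort()]).
#' @param signatures a [SignatureSet-class] (or named list coerced to one).
#' @param nBins abundance bins (default 24).
#' @param nCtrl control genes per signature gene (default 100).
#' @param seed integer seed for the control-gene draws.
#' @param minGenes minimum signature genes that must be present in the
#'   matrix (default 2).
#' @param exclude genes never drawn as controls (beyond the signature
#'   itself) — typically the contrast driver gene, whose expression
#'   defines the downstream tail stratification and must not leak into
#'   the control background.
#' @return numeric matrix, cells x signatures.
#' @export
scoreModules <- function(x, signatures, nBins = 24L, nCtrl = 100L, seed = 0L,
                         minGenes = 2L, exclude = character(0)) {
  if (!is(signatures, "SignatureSet")) signatures <- SignatureSet(signatures)
  stopifnot(nBins >= 2L, nCtrl >= 1L)
  lc <- logcounts(x)
  means <- setNames(as.numeric(Matrix::rowMeans(lc)), rownames(x))
  bins <- .abundanceBins(means, nBins)
  out <- matrix(NA_real_, ncol(x), length(signatures),
                dimnames = list(colnames(x), names(signatures)))
  for (i in seq_along(signatures@signatures)) {
    nm <- names(signatures)[i]
    sig <- .matchSignature(signatures[[i]], rownames(x), nm, minGenes)
    sigMean <- as.numeric(Matrix::colSums(lc[sig, , drop = FALSE])) / length(sig)
    w <- .withSeed(.streamSeed(seed, "controls", i),
                   .controlWeights(bins, sig, nCtrl, exclude))
    ctrlMean <- as.numeric(w %*% lc)
    out[, i] <- sigMean - ctrlMean
  }
  out
}

#' Cell-cycle phase scores
#'
#' Scores the G1/S and G2/M signatures with [scoreModules()] (independent
#' control draws from one seed stream); these are the proliferation
#' covariates of the partial-correlation analysis.
#'
#' @param x a `SingleCellExperiment` with `logcounts`.
#' @param g1s,g2m character vectors of G1/S and G2/M genes.
#' @inheritParams scoreModules
#' @return cells x 2 matrix with columns `G1S`, `G2M`.
#' @export
scoreCellCycle <- function(x, g1s, g2m, nBins = 24L, nCtrl = 100L, seed = 0L,
                           exclude = character(0)) {
  scoreModules(x, SignatureSet(list(G1S = g1s, G2M = g2m)),
               nBins = nBins, nCtrl = nCtrl, seed = seed, exclude = exclude)
}

#' Two-gene coexpression call with a blend threshold
#'
#' Each gene's log-normalized expression is min-max scaled to [0, 1]
#' across cells (optionally after percentile clipping); a cell is
#' `double_positive` if both scaled values are at or above `threshold`,
#' `A_only`/`B_only` if exactly one is, and `negative` otherwise.
#'
#' @param x a `SingleCellExperiment` with `logcounts`.
#' @param geneA,geneB gene identifiers.
#' @param threshold blend threshold in (0, 1) (default 0.15).
#' @param clip optional length-2 percentile clip (e.g. `c(0.01, 0.99)`)
#'   applied before min-max scaling; default none.
#' @return data.frame with columns `cell_id`, `label`, `scaled_a`,
#'   `scaled_b`; the threshold is attached as attribute `"threshold"`.
#' @export
classifyCoexpression <- function(x, geneA, geneB, threshold = 0.15,
                                 clip = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  scale01 <- function(gene) {
    v <- geneExpression(x, gene)
    if (!is.null(clip)) {
      qs <- quantile(v, clip, names = FALSE)
      v <- pmin(pmax(v, qs[1]), qs[2])
    }
    rng <- range(v)
    if (rng[1] == rng[2])
      stop("gene '", gene, "' has zero variance; cannot min-max scale")
    (v - rng[1]) / (rng[2] - rng[1])
  }
  a <- scale01(geneA)
  b <- scale01(geneB)
  label <- ifelse(a >= threshold & b >= threshold, "double_positive",
           ifelse(a >= threshold, "A_only",
           ifelse(b >= threshold, "B_only", "negative")))
  out <- data.frame(cell_id = colnames(x), label = label,
                    scaled_a = as.numeric(a), scaled_b = as.numeric(b),
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  out
}
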