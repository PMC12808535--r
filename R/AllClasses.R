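#' SignatureSet: an ordered collection of named gene signatures
#'
#' A lightweight container for gene sets (e.g. a chromatin-complex core
#' signature plus G1/S and G2/M cell-cycle lists).  Signature names are
#' unique; each signature is a non-empty character vector without
#' duplicates.
#'
#' @slot signatures named list of character vectors.
#'
#' @examples
#' ss <- SignatureSet(list(core = c("G1", "G2", "G3"), g1s = c("G4", "G5")))
#' names(ss)
#' ss[["core"]]
#' @export
setClass("SignatureSet", representation(signatures = "list"))

setValidity("SignatureSet", function(object) {
  sigs <- object@signatures
  if (length(sigs) == 0L) return("SignatureSet must contain >= 1 signature")
  nm <- names(sigs)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    return("all signatures must be named")
  if (anyDuplicated(nm)) return("signature names must be unique")
  for (i in seq_along(sigs)) {
    g <- sigs[[i]]
    if (!is.character(g) || length(g) == 0L)
      return(sprintf("signature '%s' is empty or not character", nm[i]))
    if (anyDuplicated(g))
      return(sprintf("signature '%s' contains duplicate genes", nm[i]))
  }
  TRUE
})

#' Construct a SignatureSet
#'
#' @param signatures named list of character vectors of gene identifiers.
#'   Duplicate genes within a signature are removed with a warning.
#' @return A [SignatureSet-class] object.
#' @export
SignatureSet <- function(signatures) {
  if (is.character(signatures)) signatures <- list(signature = signatures)
  nm <- names(signatures)
  signatures <- lapply(seq_along(signatures), function(i) {
    g <- as.character(signatures[[i]])
    if (anyDuplicated(g)) {
      warning(sprintf("signature '%s': %d duplicate gene(s) removed",
                      nm[i], sum(duplicated(g))))
      g <- unique(g)
    }
    g
  })
  names(signatures) <- nm
  new("SignatureSet", signatures = signatures)
}

#' @describeIn SignatureSet-class number of signatures
#' @param x a SignatureSet
#' @export
setMethod("length", "SignatureSet", function(x) length(x@signatures))

#' @describeIn SignatureSet-class signature names
#' @export
setMethod("names", "SignatureSet", function(x) names(x@signatures))

#' @export
setMethod("[[", "SignatureSet", function(x, i) x@signatures[[i]])

#' @export
setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet with %d signature(s)\n", length(object)))
  for (nm in names(object)) {
    g <- object@signatures[[nm]]
    cat(sprintf("  %s: %d genes (%s%s)\n", nm, length(g),
                paste(head(g, 4L), collapse = ", "),
                if (length(g) > 4L) ", ..." else ""))
  }
})

#' Signatures as a plain list
#' @param x a SignatureSet
#' @return named list of character vectors
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "SignatureSet"))
  x@signatures
}

#' MetaResult: a pooled random-effects meta-analysis
#'
#' Result of DerSimonian-Laird pooling with Hartung-Knapp inference:
#' pooled effect, between-study variance tau^2, Cochran's Q, the HK
#' standard error, t statistic, two-sided p from t with k-1 df, and the
#' per-study random-effects weights.
#'
#' @slot effect pooled effect estimate.
#' @slot tau2 DerSimonian-Laird between-study variance (>= 0).
#' @slot Q Cochran's Q statistic.
#' @slot k number of studies pooled.
#' @slot se Hartung-Knapp standard error.
#' @slot ci lower/upper confidence bounds (length 2).
#' @slot level confidence level.
#' @slot tstat t statistic effect / se.
#' @slot p two-sided p-value from t_{k-1}.
#' @slot weights per-study random-effects weights 1/(v_i + tau2).
#' @slot excluded data.frame of excluded studies and reasons.
#'
#' @export
setClass("MetaResult", representation(
  effect = "numeric", tau2 = "numeric", Q = "numeric", k = "integer",
  se = "numeric", ci = "numeric", level = "numeric", tstat = "numeric",
  p = "numeric", weights = "numeric", excluded = "data.frame"))

setValidity("MetaResult", function(object) {
  if (object@tau2 < 0) return("tau2 must be >= 0")
  if (object@k < 2L) return("k must be >= 2")
  if (length(object@ci) != 2L || object@ci[1] > object@ci[2])
    return("ci must be [lo, hi] with lo <= hi")
  if (object@effect < object@ci[1] - 1e-12 || object@effect > object@ci[2] + 1e-12)
    return("pooled effect must lie inside its CI")
  if (object@p <= 0 || object@p > 1) return("p must be in (0, 1]")
  TRUE
})

#' @export
setMethod("show", "MetaResult", function(object) {
  cat("Random-effects meta-analysis (DerSimonian-Laird tau2, Hartung-Knapp)\n")
  cat(sprintf("  k = %d studies\n", object@k))
  cat(sprintf("  pooled effect = %.6g  [%d%% CI %.6g, %.6g]\n",
              object@effect, round(100 * object@level),
              object@ci[1], object@ci[2]))
  cat(sprintf("  tau2 = %.6g, Q = %.6g, se(HK) = %.6g\n",
              object@tau2, object@Q, object@se))
  cat(sprintf("  t = %.4g, p = %s\n", object@tstat,
              if (object@p <= 1e-300) "< 1e-300" else format(object@p)))
  if (nrow(object@excluded))
    cat(sprintf("  %d stud%s excluded\n", nrow(object@excluded),
                if (nrow(object@excluded) == 1L) "y" else "ies"))
})

#' @describeIn MetaResult-class pooled effect estimate
#' @param object a MetaResult
#' @export
pooledEffect <- function(object) object@effect

#' @describeIn MetaResult-class between-study variance
#' @export
tau2 <- function(object) object@tau2

#' @describeIn MetaResult-class confidence interval (length-2 numeric)
#' @export
metaCI <- function(object) object@ci

#' @describeIn MetaResult-class two-sided p-value
#' @export
metaP <- function(object) object@p

#' CorMetaResult: correlation meta-analysis on the Fisher-z scale
#'
#' Extends [MetaResult-class]; the pooled effect, CI and p live on the
#' z = atanh(r) scale, and `rEffect`/`rCI` carry the tanh back-transform.
#'
#' @slot rEffect pooled correlation tanh(effect).
#' @slot rCI back-transformed CI on the r scale.
#' @export
setClass("CorMetaResult", contains = "MetaResult",
         representation(rEffect = "numeric", rCI = "numeric"))

setValidity("CorMetaResult", function(object) {
  if (abs(object@rEffect) >= 1) return("|pooled r| must be < 1")
  if (any(abs(object@rCI - tanh(object@ci)) > 1e-12))
    return("r-scale CI must be tanh of the z-scale CI")
  TRUE
})

#' @export
setMethod("show", "CorMetaResult", function(object) {
  callNextMethod()
  cat(sprintf("  pooled r = %.6g  [r-scale CI %.6g, %.6g]\n",
              object@rEffect, object@rCI[1], object@rCI[2]))
})

#' @describeIn CorMetaResult-class pooled correlation on the r scale
#' @param object a CorMetaResult
#' @export
pooledR <- function(object) object@rEffect

#' NullDistribution: matched random gene-set null for specificity
#'
#' Pooled effects of size/abundance-matched random gene sets, the
#' observed pooled effect of the target signature, and the add-one
#' two-sided empirical p-value
#' `(1 + #\{|null| >= |observed|\}) / (R + 1)`.
#'
#' @slot observed observed pooled effect of the target signature.
#' @slot nullEffects pooled effects of the matched random sets.
#' @slot empiricalP add-one two-sided empirical p.
#' @slot nReps number of null replicates requested.
#' @slot failed data.frame of failed replicates with reasons.
#' @export
setClass("NullDistribution", representation(
  observed = "numeric", nullEffects = "numeric", empiricalP = "numeric",
  nReps = "integer", failed = "data.frame"))

setValidity("NullDistribution", function(object) {
  R <- length(object@nullEffects)
  if (R < 1L) return("need >= 1 successful null replicate")
  expP <- (1 + sum(abs(object@nullEffects) >= abs(object@observed))) / (R + 1)
  if (abs(object@empiricalP - expP) > 1e-12)
    return("empiricalP inconsistent with the add-one rule")
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empiricalP must be in (0, 1]")
  TRUE
})

#' @export
setMethod("show", "NullDistribution", function(object) {
  cat("Size/abundance-matched random gene-set null\n")
  cat(sprintf("  observed pooled effect = %.6g\n", object@observed))
  cat(sprintf("  null replicates: %d successful / %d requested\n",
              length(object@nullEffects), object@nReps))
  cat(sprintf("  two-sided empirical p = %.4g\n", object@empiricalP))
})

#' @describeIn NullDistribution-class add-one two-sided empirical p
#' @param object a NullDistribution
#' @export
empiricalP <- function(object) object@empiricalP

#' @describeIn NullDistribution-class null pooled effects
#' @export
nullEffects <- function(object) object@nullEffects
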