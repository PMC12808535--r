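#' DerSimonian-Laird between-study variance
#'
#' Moment estimator from Cochran's Q: with fixed-effect weights
#' `w_i = 1/v_i`,
#' `Q = sum w_i (y_i - mu_FE)^2` and
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`.
#'
#' @param effects numeric vector of study effects (k >= 2).
#' @param variances positive within-study variances.
#' @return list with `tau2` and `Q`.
#' @export
dlTau2 <- function(effects, variances) {
  k <- length(effects)
  if (k < 2L) stop("meta-analysis needs >=2 studies")
  stopifnot(length(variances) == k, all(variances > 0))
  w <- 1 / variances
  muFE <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - muFE)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / denom)
  list(tau2 = tau2, Q = Q)
}

#' Random-effects pooled estimate
#'
#' Inverse-variance pooling with weights `w*_i = 1/(v_i + tau2)`.
#'
#' @inheritParams dlTau2
#' @param tau2 between-study variance (>= 0).
#' @return list with `mu` (pooled effect) and `weights`.
#' @export
poolRandomEffects <- function(effects, variances, tau2) {
  stopifnot(length(effects) >= 2L, tau2 >= 0)
  w <- 1 / (variances + tau2)
  list(mu = sum(w * effects) / sum(w), weights = w)
}

#' Hartung-Knapp standard error, CI and test
#'
#' `q = 1/(k-1) * sum w*_i (y_i - mu)^2`, `se = sqrt(q / sum w*)`,
#' CI `mu +/- t_{k-1, (1+level)/2} * se`, two-sided p from `t_{k-1}`.
#' By default `q` is not truncated (the original Hartung-Knapp
#' estimator); `floorQ = TRUE` applies the `max(q, 1)` modification.
#' A degenerate `se` (all effects equal) is floored at 1e-12 and p at
#' 1e-300.
#'
#' @inheritParams poolRandomEffects
#' @param mu pooled random-effects estimate.
#' @param level confidence level (default 0.95).
#' @param floorQ apply the modified-HK `max(q, 1)` floor (default FALSE).
#' @return list with `se`, `ci` (length 2), `tstat`, `p`, `df`.
#' @export
hkInference <- function(effects, variances, tau2, mu, level = 0.95,
                        floorQ = FALSE) {
  k <- length(effects)
  if (k < 2L) stop("Hartung-Knapp inference needs >=2 studies (df = k-1)")
  stopifnot(level > 0, level < 1)
  w <- 1 / (variances + tau2)
  q <- sum(w * (effects - mu)^2) / (k - 1)
  if (floorQ) q <- max(q, 1)
  se <- max(sqrt(q / sum(w)), 1e-12)
  tcrit <- qt((1 + level) / 2, df = k - 1)
  tstat <- mu / se
  p <- max(2 * pt(-abs(tstat), df = k - 1), 1e-300)
  list(se = se, ci = c(mu - tcrit * se, mu + tcrit * se),
       tstat = tstat, p = p, df = k - 1L)
}

#' Random-effects meta-analysis (DL tau2 + HK inference)
#'
#' Composes [dlTau2()], [poolRandomEffects()] and [hkInference()].
#'
#' @inheritParams dlTau2
#' @inheritParams hkInference
#' @param excluded optional data.frame of excluded studies (carried into
#'   the result for provenance).
#' @return A [MetaResult-class].
#' @export
metaAnalyze <- function(effects, variances, level = 0.95, floorQ = FALSE,
                        excluded = data.frame()) {
  dl <- dlTau2(effects, variances)
  re <- poolRandomEffects(effects, variances, dl$tau2)
  hk <- hkInference(effects, variances, dl$tau2, re$mu, level, floorQ)
  new("MetaResult", effect = re$mu, tau2 = dl$tau2, Q = dl$Q,
      k = length(effects), se = hk$se, ci = hk$ci, level = level,
      tstat = hk$tstat, p = hk$p, weights = re$weights,
      excluded = excluded)
}

#' Meta-analysis of per-patient tail contrasts
#'
#' Pools the eligible rows of a [patientContrasts()] table; ineligible
#' patients are recorded in the result's `excluded` slot.
#'
#' @param contrasts data.frame from [patientContrasts()].
#' @inheritParams hkInference
#' @param floorQ see [hkInference()].
#' @return A [MetaResult-class].
#' @export
metaAnalyzeContrasts <- function(contrasts, level = 0.95, floorQ = FALSE) {
  ok <- contrasts$eligible
  excl <- data.frame(patient_id = contrasts$patient_id[!ok],
                     reason = contrasts$reason[!ok])
  if (sum(ok) < 2L)
    stop("meta-analysis needs >=2 eligible patients; exclusions: ",
         paste(sprintf("%s (%s)", excl$patient_id, excl$reason),
               collapse = "; "))
  metaAnalyze(contrasts$delta[ok], contrasts$variance[ok], level = level,
              floorQ = floorQ, excluded = excl)
}

#' Meta-analysis of Fisher-z partial correlations
#'
#' Pools per-patient partial correlations on the z = atanh(r) scale with
#' variance `1/(n_i - 3 - c)` (the degrees-of-freedom correction for c
#' covariates; `dfCorrection = FALSE` uses the plain `1/(n_i - 3)`), via
#' DL + HK, and back-transforms the pooled estimate and CI with tanh.
#' Patients with `n_i <= c + 3` are excluded with a logged reason.
#'
#' @param pcs data.frame from [patientPartialCorrelations()].
#' @inheritParams hkInference
#' @param floorQ see [hkInference()].
#' @param dfCorrection subtract the covariate count from the Fisher-z
#'   degrees of freedom (default TRUE).
#' @return A [CorMetaResult-class].
#' @export
metaAnalyzeCorrelations <- function(pcs, level = 0.95, floorQ = FALSE,
                                    dfCorrection = TRUE) {
  dfc <- if (dfCorrection) pcs$c else rep(0L, nrow(pcs))
  ok <- pcs$n > pcs$c + 3L
  if (any(!ok))
    .msg(sum(!ok), " patient(s) excluded from correlation meta (n <= c + 3)")
  excl <- data.frame(patient_id = pcs$patient_id[!ok],
                     reason = rep("n <= c + 3", sum(!ok)))
  if (sum(ok) < 2L) stop("correlation meta-analysis needs >=2 usable patients")
  vi <- 1 / (pcs$n[ok] - 3 - dfc[ok])
  base <- metaAnalyze(pcs$z[ok], vi, level = level, floorQ = floorQ,
                      excluded = excl)
  new("CorMetaResult", base, rEffect = tanh(base@effect),
      rCI = tanh(base@ci))
}
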