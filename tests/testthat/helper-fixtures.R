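suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(Matrix)
})

# SCE with a hand-crafted logcounts matrix (genes x cells), bypassing
# normalization, for scoring tests that need exact expression values.
sceFromLogcounts <- function(lc, patient = NULL) {
  cnt <- matrix(1L, nrow(lc), ncol(lc), dimnames = dimnames(lc))
  x <- makeCohort(cnt, patient = patient)
  logcounts(x) <- lc
  x
}

randomLogcounts <- function(nGenes, nCells, seed = 1) {
  withr::with_seed(seed, {
    lc <- matrix(abs(rnorm(nGenes * nCells)), nGenes, nCells)
    dimnames(lc) <- list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("c%03d", seq_len(nCells)))
    lc
  })
}

# Independent, loop-coded re-derivation of the DL + HK closed forms,
# kept deliberately naive (scalar accumulation, no shared code with the
# package) to serve as the reference implementation in tests.
bruteMeta <- function(y, v, level = 0.95) {
  k <- length(y)
  sw <- 0; swy <- 0
  for (i in 1:k) { sw <- sw + 1 / v[i]; swy <- swy + y[i] / v[i] }
  muFE <- swy / sw
  Q <- 0; sw2 <- 0
  for (i in 1:k) {
    Q <- Q + (y[i] - muFE)^2 / v[i]
    sw2 <- sw2 + (1 / v[i])^2
  }
  tau2 <- (Q - (k - 1)) / (sw - sw2 / sw)
  if (tau2 < 0) tau2 <- 0
  sws <- 0; swys <- 0
  for (i in 1:k) { sws <- sws + 1 / (v[i] + tau2); swys <- swys + y[i] / (v[i] + tau2) }
  mu <- swys / sws
  q <- 0
  for (i in 1:k) q <- q + (y[i] - mu)^2 / (v[i] + tau2)
  q <- q / (k - 1)
  se <- sqrt(q / sws)
  tc <- qt((1 + level) / 2, k - 1)
  list(tau2 = tau2, Q = Q, mu = mu, se = se,
       ci = c(mu - tc * se, mu + tc * se),
       p = 2 * pt(-abs(mu / se), k - 1))
}
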