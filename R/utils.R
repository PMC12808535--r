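#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnorm rnbinom rgamma rlnorm runif var cor pt qt sd
#'   complete.cases setNames quantile p.adjust
#' @importFrom utils head read.delim write.table
NULL

# Deterministic sub-seed for a named random stream.  A single root seed is
# expanded into independent, individually reproducible streams (control-gene
# draws, null-set draws, simulator blocks) so perturbing one stage does not
# reshuffle the others.  Kept below 2^31 - 1.
.streamSeed <- function(seed, stream, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 7919 + h + as.numeric(index) * 104729) %%
               2147483629)
}

# Run expr with a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

.msg <- function(...) message("[scContrastMeta] ", ...)

# radix order: locale-independent, ties resolved by later keys
.orderStable <- function(...) order(..., method = "radix")
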