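# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive an independent substream seed from a master seed.  Keeps results
# of one stage unchanged when another stage consumes more random numbers.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert log2 fold change to the signed linear-scale convention
#'
#' Up-regulation is reported as the plain ratio (`+r`, r >= 1) and
#' down-regulation as the negative reciprocal ratio (`-1/r` style), so a
#' halving appears as -2 rather than 0.5. This is the convention used in
#' published differential-expression tables for vascular transcriptomics.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return numeric vector of signed linear fold changes; `sign(out) ==
#'   sign(log2fc)` and `abs(out) == 2^abs(log2fc)` (zero maps to +1).
#' @examples
#' signed_fc(c(2, 0, -1.07))  # +4, +1, ~ -2.10
#' @export
signed_fc <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}
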