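# Internal helpers shared across modules.

#' Robust standard deviation
#'
#' Scaled median absolute deviation, `1.4826 * mad`, the robust spread
#' estimate used for stain indices and the interference screen.
#'
#' @param x Numeric vector.
#' @return A single number; consistent with the SD under normality.
#' @keywords internal
robust_sd <- function(x) {
  stats::mad(x, constant = 1.4826)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation helpers never perturb
# user-level randomness.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stable 31-bit string hash (polynomial, mod 2^31 - 1). Used to derive
# per-sample RNG substreams from (seed, donor, condition, replicate, stain)
# so that adding samples to a cohort never perturbs existing ones.
stable_hash <- function(...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Derive a child seed below 2^31 from a base seed and key components.
substream_seed <- function(seed, ...) {
  stable_hash(as.integer(seed), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
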