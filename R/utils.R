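# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from an experiment-level seed
#'
#' All randomness in the package fans out from a single experiment seed.
#' Named stages (tone phases, noise, interval order, per-child observers,
#' ...) each get their own deterministic sub-seed so that changing one
#' stage's draws never perturbs another's.
#'
#' @param seed integer master seed.
#' @param key character stage name, or an integer offset.
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
substream <- function(seed, key) {
  if (is.character(key)) {
    # cheap string hash, stable across platforms
    key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  as.integer((as.numeric(seed) * 48271 + as.numeric(key) * 16807) %% m)
}

# Evaluate `expr` under set.seed(seed) without clobbering the caller's
# RNG state. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Raised-cosine on/off gate of `ramp` seconds applied in place.
apply_ramp <- function(x, ramp, sample_rate) {
  n <- length(x)
  nr <- round(ramp * sample_rate)
  if (nr < 1) return(x)
  stopifnot(2 * nr <= n)
  gate <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
  x[1:nr] <- x[1:nr] * gate
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(gate)
  x
}

rms <- function(x) sqrt(mean(x^2))

peak_normalize <- function(x, peak = 0.95) {
  m <- max(abs(x))
  if (m == 0) return(x)
  x * (peak / m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
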