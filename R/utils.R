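## error function via the normal CDF
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## run code under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
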