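# Seed scoping: set a seed for a reproducible block, then restore whatever
# RNG state the caller had (pattern as in withr::with_seed).
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Population (divisor-n) variance
pop_var <- function(x) mean((x - mean(x))^2)
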