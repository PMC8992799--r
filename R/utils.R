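#' @importFrom rlang .data abort warn %||%
#' @importFrom stats rnorm runif rbinom optim cor sd coef lm p.adjust dist
#' @importFrom utils head tail
NULL

# z-score with population (n) standard deviation, for bit-exact comparability
# with vectorised RDM regression oracles
zscore_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    abort("cannot z-score a constant vector")
  }
  (x - mu) / s
}

# lower-triangle vectorisation (column-major, excluding the diagonal)
lower_tri_vec <- function(m) {
  m[lower.tri(m)]
}

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards. All package randomness funnels through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive per-replicate child seeds from a master seed, kept below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

relu <- function(x) {
  x * (x > 0)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
}
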