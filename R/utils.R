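## internal helpers shared across modules

## Evaluate expr with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards.  All generators route their randomness through
## this so they are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a stream-specific sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k * 1009) %% 2147483647)
}

## robust standard deviation: 1.4826 * median absolute deviation
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

## log-normal draws with a given arithmetic mean and coefficient of
## variation; cv = 0 degenerates to the exact mean (zero-noise contract)
rlnorm_mean_cv <- function(n, mean, cv) {
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (cv <= 0) return(mean)
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(pmax(mean, .Machine$double.xmin)) - sdlog^2 / 2,
                sdlog = sdlog)
}

## column-wise medians of a matrix
col_medians <- function(m) apply(m, 2L, stats::median)

`%||%` <- function(a, b) if (is.null(a)) b else a
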