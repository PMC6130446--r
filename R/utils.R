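#' Derive a reproducible child seed from a master seed
#'
#' Stages of the pipeline (simulation, per-run resampling, permutation nulls)
#' each need their own random stream. A single master seed is hashed together
#' with a stage tag so that 1,000-run experiments are reproducible without
#' storing 1,000 seeds. The result always fits in a 32-bit integer.
#'
#' @param seed master seed (single integer).
#' @param tag character tag naming the consumer, or an integer offset.
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (is.character(tag)) {
    tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  }
  x <- (abs(as.numeric(seed)) %% 2147483647) + 1
  # two rounds of a Lehmer-style mix keep distinct tags well separated
  x <- (x * 48271 + as.numeric(tag) * 16807) %% 2147483647
  x <- (x * 69621 + 12345) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# run-length spans of TRUE in a logical vector, as a two-column matrix
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cohen_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (!is.finite(sp) || sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}
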