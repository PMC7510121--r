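# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Splits one master seed into independent per-task seeds (per scene, per
#' tile, per fold) so that a single `--seed` reproduces a whole run. Values
#' stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  # all arithmetic exact in doubles (< 2^53)
  s <- (abs(as.numeric(master)) %% 2147483647) + 1
  x <- (s * 48271 + as.numeric(index) * 100003 + 12345) %% 2147483647
  as.integer(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Deterministic uniform in [0,1) from (seed, id); used for per-instance
# decisions that must not depend on tile visit order.
hash_unif <- function(seed, id) {
  x <- (as.numeric(seed) * 2654435761 + as.numeric(id) * 97531 + 7) %% 2147483629
  x <- (x * 16807) %% 2147483647
  x / 2147483647
}

# Run-length encoding of a sorted vector of linear pixel indices.
rle_encode <- function(idx) {
  if (length(idx) == 0L) return(list(starts = integer(0), lengths = integer(0)))
  idx <- sort(as.integer(idx))
  brk <- c(TRUE, diff(idx) != 1L)
  starts <- idx[brk]
  grp <- cumsum(brk)
  lens <- as.integer(tabulate(grp))
  list(starts = starts, lengths = lens)
}

rle_decode <- function(starts, lengths) {
  if (length(starts) == 0L) return(integer(0))
  out <- sequence(lengths)
  rep(as.integer(starts), lengths) + out - 1L
}

# standard error of the mean; NA for n < 2
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
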