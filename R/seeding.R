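#' Derive a reproducible child seed from a master seed
#'
#' Hierarchical seeding: a master seed plus a path of integer indices (for
#' example subsample number, replicate number) is hashed to an independent
#' seed.  Any draw in the pipeline is a pure function of
#' `(master_seed, subsample, replicate)`, so runs parallelise deterministically.
#'
#' @param master integer master seed.
#' @param ... further non-negative integers identifying the stream (the path).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, 2, 3)
#' @export
derive_seed <- function(master, ...) {
  path <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (v in path) {
    stopifnot(is.finite(v))
    h <- (h * 48271 + (v %% m) + 11) %% m
    # one extra multiplicative mix so (a, b) and (a + 48271 * b) differ
    h <- (h * 69621) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the previous state on exit.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
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
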