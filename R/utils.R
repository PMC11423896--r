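#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so generators do not perturb each other.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

#' Derive a stage seed from a global seed
#'
#' Deterministic integer hash of (seed, label), kept below 2^31 so it is a
#' valid R integer. Every random stage of the pipeline draws its own seed
#' through this, so stages are independently reproducible.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483399 + 1)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
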