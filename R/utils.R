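#' Run code with a local, restorable random seed
#'
#' All stochastic routines in the package take an explicit integer seed and
#' restore the caller's RNG state on exit, so no function mutates global
#' RNG state as a side effect.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Numerically stable log-sum-exp
#' @param x numeric vector.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_dims <- function(what, got, want) {
  stop(sprintf("dimension mismatch: %s has length/size %s, expected %s",
               what, paste(got, collapse = "x"), paste(want, collapse = "x")),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
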