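#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers/tests can match on error class
#' @noRd
stop_mobidt <- function(class, msg) {
  stop(structure(class = c(class, "mobidt_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Set the RNG deterministically for a generator call
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_mobidt("invalid_config", "seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Excess-free (MATLAB-style) kurtosis: m4 / m2^2
#' @noRd
kurtosis_moment <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NA_real_)
  mean(x^4) / m2^2
}
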