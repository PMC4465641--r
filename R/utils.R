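# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Run an expression under a fixed RNG state without disturbing the caller's
# stream. All stochastic internals (homology-test shuffles, null-model draws)
# go through this so results are reproducible from function arguments alone.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
}

# Largest-remainder apportionment of `n` items to proportions `p` (named).
# Deterministic: remainders tie-broken by name order.
apportion <- function(n, p) {
  if (is.null(n) || n == 0L)
    return(stats::setNames(integer(length(p)), names(p)))
  p <- p / sum(p)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(-(raw - k), names(p))
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  as.integer(k)
}
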