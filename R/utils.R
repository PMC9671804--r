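#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG state without disturbing the caller's
# stream. All exported stochastic functions route through this so that a
# given seed is reproducible regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label; keeps
# sub-generators independent while still fully determined by one seed.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  s <- utf8ToInt(as.character(stream))
  h <- sum(s * seq_along(s))
  # double arithmetic stays exact well past 2^31 * 1009; reduce mod a prime
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
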