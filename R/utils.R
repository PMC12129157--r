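# internal helpers shared across the package

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# derive a distinct 31-bit sub-seed from a base seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) (x > 0) * x
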