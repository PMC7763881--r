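# evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards (keeps independent streams per artifact)
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# round count mid-parent values half-up to integers
roundHalfUp <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
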