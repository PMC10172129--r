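# internal helpers shared across modules

# run code with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so no hidden global state leaks
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# derive a stream of child seeds (< 2^31) from one seed
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

usage_error <- function(msg) {
  stop(structure(class = c("lsb_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

data_error <- function(msg) {
  stop(structure(class = c("lsb_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
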