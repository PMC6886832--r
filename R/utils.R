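# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Classed conditions so callers can distinguish failure modes programmatically.
msig_stop <- function(message, class) {
  stop(structure(
    class = c(class, "metabosig_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

# sample() without the scalar-x surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}
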