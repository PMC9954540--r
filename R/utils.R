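# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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

stop_p300 <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "p300bci_error")))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stop_p300("`%s` must be a single integer >= %d (got %s)", name, min,
              paste(format(x), collapse = ","), class = "parameter_error")
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_p300("`%s` must be a single positive number", name,
              class = "parameter_error")
  }
  as.numeric(x)
}
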