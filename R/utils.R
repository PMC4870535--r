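## Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Scalar checks used by configuration validators; `name` makes the error
# message point at the offending field.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("field '%s' must be a single finite number", name),
         call. = FALSE)
  }
  if (integer && x != trunc(x)) {
    stop(sprintf("field '%s' must be an integer", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("field '%s' must be in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Sample standard deviation guarded against degenerate populations.
sd_checked <- function(x, name) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("degenerate population '%s': zero or undefined spread",
                 name), call. = FALSE)
  }
  s
}
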