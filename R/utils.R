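# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ep <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_ep("'%s' must be a single positive finite number", name)
  invisible(x)
}

# Derive a stream of child seeds from one master seed; keeps every seed
# within 32-bit integer range so set.seed() never overflows.
derive_seeds <- function(seed, n, salt = 0L) {
  seed <- as.integer(seed)
  (as.double(seed) * 48271 + salt * 65537 + seq_len(n) * 2654435761) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}
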