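#' @keywords internal
"_PACKAGE"

# Shared internal helpers: argument checking and seeded RNG scoping.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bci <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_bci("non-finite values in %s", what)
  invisible(x)
}

# Evaluate `expr` under a deterministic RNG state without disturbing the
# caller's stream. Seeds are kept below 2^31 - 1.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% 2147483647L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mix several small integers into one sub-seed (stays in 32-bit range).
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(h)
}

clamp01 <- function(x) pmin(1, pmax(0, x))
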