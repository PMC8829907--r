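# Internal helpers shared across modules.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fold one base seed and any number of integer salts into a derived seed in
# [0, 2^31 - 2]; keeps every stream in the package reproducible from one seed.
derive_seed <- function(seed, ...) {
  xs <- c(seed, ...)
  p <- 2147483647
  h <- 0
  for (x in xs) {
    h <- (h * 48271 + (as.numeric(x) %% p) + 11) %% p
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "dnakv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x)
}

is_fraction <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= lo && x <= hi
}
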