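# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_user <- function(...) stop(..., call. = FALSE)

# Deterministic 31-bit sub-seed from a master seed and a stream index, so
# per-exposure (or per-frame) random streams are independent but reproducible.
derive_seed <- function(master, stream) {
  master <- as.double(master) %% 2147483647
  s <- (master * 48271 + as.double(stream) * 16807 + 12345) %% 2147483647
  as.integer(s)
}

# Run code under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
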