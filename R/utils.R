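# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed and restore the caller's RNG state
# afterwards, so seeded operations compose without side effects.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
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
  force(code)
}

#' Derive a run seed from a master seed
#'
#' Deterministic splitting rule used by the sweep orchestrators so that every
#' (level, run) cell of an experiment gets its own reproducible seed. The
#' result is always a positive integer below 2^31.
#'
#' @param master Master seed (integer).
#' @param a,b Non-negative integer indices (e.g. level index and run index).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, a, b = 0L) {
  m <- as.numeric(master) %% 100003
  s <- (m * 10007 + as.numeric(a) * 7919 + as.numeric(b) * 97) %% 2147483646
  as.integer(s) + 1L
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Cheap stable digest of an R object (no external digest dependency):
# serialises to characters and folds into a 32-bit hex string.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = " ")
  v <- utf8ToInt(txt)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
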