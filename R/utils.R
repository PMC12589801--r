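# Internal helpers: argument checking and deterministic seed streams.

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_domain(sprintf("`%s` must be a single non-negative finite number", name))
  }
  invisible(x)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used to give every repeat / condition / Monte
#' Carlo loop its own independent RNG stream while staying reproducible from
#' a single master seed. Results stay inside the 32-bit integer range R
#' requires of `set.seed()`.
#'
#' @param master_seed integer master seed.
#' @param index positive integer stream index.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(master_seed, index) {
  # 64-bit-safe multiplicative hash folded into [0, 2^31 - 2]
  x <- (as.double(master_seed) %% 2147483647) + 1
  for (k in seq_len(index %% 7L + 1L)) {
    x <- (x * 48271) %% 2147483647
  }
  as.integer((x + 99991 * as.double(index)) %% 2147483646) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
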