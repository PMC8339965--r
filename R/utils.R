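#' @importFrom stats cor predict qnorm quantile rbinom rnorm runif sd setNames
#' @importFrom utils head tail
#' @importFrom dplyr .data
NULL

# Stable 32-bit polynomial string hash (FNV-1a style), used to derive
# reproducible per-token seeds and sub-seeds. Kept < 2^31 so it is always a
# valid R integer seed.
str_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2^31)
}

# Derive a child seed from a base seed and one or more labels/indices.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  str_hash(parts)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_data <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
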