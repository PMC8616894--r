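#' Derive a reproducible sub-seed from a base seed and a stream name
#'
#' A single experiment seed fans out to independent, named RNG streams
#' (phantom geometry, label sampling, augmentation, weight initialization,
#' batch order, ...) so that adding draws to one stream never perturbs
#' another. The derivation is a small FNV-1a style hash of the name folded
#' into the base seed, kept strictly below 2^31.
#'
#' @param seed integer base seed.
#' @param name character stream name.
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((abs(seed) + h) %% 2^31)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# lightweight FNV-1a hash of a serialized R object, as a hex string;
# used to stamp run manifests
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  # fold in 4-byte words to keep the loop short
  ints <- readBin(raw, "integer", n = length(raw) %/% 4L, size = 4L)
  for (v in ints) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(abs(v) %% 2^31))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
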