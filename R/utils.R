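# Internal helpers shared across modules.

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted: symbols from different sources must already use the same
#' nomenclature (documented limitation).
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x))) stop("empty gene symbol after normalization")
  if (any(grepl("[[:space:]]", x))) stop("gene symbols must not contain whitespace")
  x
}

# Deterministic sub-seed derivation: one master seed fans out to independent
# per-generator streams so changing one generator's draws never perturbs
# another's. Offsets are fixed per generator (documented in the vignette).
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) + 104729 * k) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All generators route randomness through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
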