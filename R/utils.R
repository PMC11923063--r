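# Internal helpers shared across modules.

#' The 20 standard amino acids
#'
#' One-letter codes in the conventional alphabetical order.
#' @export
AA_STANDARD_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package are
# funnelled through this so that a single seed argument reproduces results
# without clobbering the session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
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

# Derive a child seed from a run seed and a stream label, staying inside the
# 32-bit integer range.
childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 1009 + h) %% 2147483647)
}

# Key used throughout for one enzyme-substrate pair.
pairKey <- function(sequence, smiles) paste(sequence, smiles, sep = "\r")

stopIfNotScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string")
}
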