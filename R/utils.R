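## internal helpers: rounding, column statistics, seeded evaluation

# round half away from zero (R's round() is banker's rounding)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# evaluate expr under a given RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named child RNG seed
#'
#' Splits one top-level seed into independent named streams (for example
#' \code{"simulate"} and \code{"permute"}) so that components consuming
#' randomness do not share a stream. Purely arithmetic; the result is a
#' valid 32-bit seed.
#'
#' @param seed integer top-level seed.
#' @param stream character stream name.
#' @return An integer seed.
#' @examples
#' childSeed(17, "simulate")
#' @export
childSeed <- function(seed, stream) {
  v <- utf8ToInt(as.character(stream))
  h <- sum(v * seq_along(v)) %% 65521
  as.integer((((as.double(seed) %% 65521) * 65519) + h * 2654435 + 7) %% 2147483629)
}

#' Reverse complement of DNA words
#'
#' Thin character-vector wrapper around
#' \link[Biostrings]{reverseComplement}.
#'
#' @param x character vector of A/C/G/T words.
#' @return Character vector of reverse complements.
#' @examples
#' revComp(c("ACGT", "TGTTGA"))
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
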