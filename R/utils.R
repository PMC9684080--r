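#' Derive a stage-specific child seed from a global seed
#'
#' A single cohort seed fans out to per-stage child seeds through a
#' counter-based arithmetic scheme, so that individual simulation stages can
#' be re-run independently and still reproduce exactly.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"fragments"`) or an integer
#'   counter.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  counter <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.integer(stage)
  }
  as.integer((abs(seed) * 69091 + counter * 1299721 + 12345) %% 2147483647)
}

#' Cosine similarity between two non-negative vectors
#'
#' @param a,b Numeric vectors of equal length; at least one entry of each
#'   must be non-zero.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}

## The 96 single-base-substitution channels in COSMIC order: six pyrimidine
## substitution types, each in 16 trinucleotide contexts.
sbs_substitutions <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Names of the 96 substitution channels
#'
#' Channels are labelled `X[R>A]Y` where `R>A` is the pyrimidine-strand
#' substitution and `X`, `Y` the 5' and 3' flanking bases.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (sub in sbs_substitutions) {
    ref <- substr(sub, 1, 1)
    for (five in bases) {
      for (three in bases) {
        out <- c(out, paste0(five, "[", sub, "]", three))
      }
    }
  }
  out
}

#' Trinucleotide context of each substitution channel
#'
#' @return Character vector of length 96 giving, for each channel of
#'   [sbs96_channels()], its pyrimidine-strand trinucleotide context (one of
#'   32 contexts).
#' @export
sbs96_contexts <- function() {
  ch <- sbs96_channels()
  paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
}

#' The 32 pyrimidine-centred trinucleotide contexts
#' @return Character vector of length 32.
#' @export
trinucleotide_contexts <- function() {
  unique(sbs96_contexts())
}

## internal: run code with a local RNG state so generators do not disturb
## the caller's random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
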