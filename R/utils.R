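#' Derive a stage seed from a global seed
#'
#' All simulators in the package take an integer seed. Pipelines that run
#' several stochastic stages derive one sub-seed per stage from the single
#' run seed with this function, keeping the whole run reproducible from one
#' integer while decorrelating the stage RNG streams.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (any small non-negative integer).
#' @return An integer in [0, 2^31 - 2] usable with [set.seed()].
#' @examples
#' deriveSeed(1L, 3L)
#' @export
deriveSeed <- function(seed, offset = 0L) {
  # Lehmer-style mix; all quantities stay below 2^53 so doubles are exact.
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer(((s * 48271) + as.numeric(offset) * 9973) %% 2147483647)
}

# random DNA string of length n under the current RNG stream
.randomDna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reverse complement for plain character vectors
.revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' The package stores annotation in `GRanges` (1-based inclusive, the
#' Bioconductor convention) but all tabular interfaces (alignment tables,
#' positional profiles, provenance, BED) use 0-based half-open coordinates.
#' This helper converts the latter into the former; `[10, 20)` on the plus
#' strand becomes positions 11..20.
#'
#' @param chrom character vector of reference names.
#' @param start0,end0 0-based half-open interval bounds.
#' @param strand strand characters ("+", "-" or "*").
#' @return A [GenomicRanges::GRanges] object.
#' @examples
#' granges0("chrI", 10, 20)
#' @export
granges0 <- function(chrom, start0, end0, strand = "*") {
  stopifnot(all(end0 > start0))
  GRanges(chrom, IRanges(start = start0 + 1L, end = end0), strand = strand)
}

# weighted sum of `w` into positions `idx1` (1-based) of a length-L vector
.accumulate <- function(idx1, w, L) {
  out <- numeric(L)
  if (length(idx1)) {
    s <- tapply(w, idx1, sum)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}
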