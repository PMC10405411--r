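#' Write reads as FASTQ
#'
#' Qualities are constant maximal ("I", Phred 40); no downstream step uses
#' quality. Writing then reading a set reproduces identifiers and
#' sequences exactly.
#'
#' @param x a \linkS4class{ReadSet} or a named [Biostrings::DNAStringSet].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeReads <- function(x, path) {
  rd <- if (is(x, "ReadSet")) x@reads else x
  qual <- BStringSet(vapply(BiocGenerics::width(rd), function(w)
    strrep("I", w), character(1)))
  writeXStringSet(rd, filepath = path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFastqReads <- function(path) {
  readDNAStringSet(path, format = "fastq")
}

#' Write / read a ground-truth provenance table
#'
#' Tab-separated with columns read_id, substrate, start0, end0, strand,
#' n_mutations; coordinates 0-based half-open.
#'
#' @param x a \linkS4class{ReadSet} or a provenance data.frame.
#' @param path output TSV path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
writeProvenance <- function(x, path) {
  pv <- if (is(x, "ReadSet")) x@provenance else x
  write.table(pv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProvenance
#' @export
readProvenance <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an alignment table
#'
#' Tab-separated with the columns produced by [alignReads()]: read_id,
#' reference, start0, length, strand, mismatches, weight, seq.
#'
#' @param aln alignment data.frame.
#' @param path TSV path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
writeAlignments <- function(aln, path) {
  write.table(aln, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlignments
#' @export
readAlignments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a positional profile as TSV
#'
#' One row per position: reference, pos0, plus_weight, minus_weight.
#'
#' @param profile profile list from [fivePrimeProfile()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  df <- data.frame(reference = profile$reference,
                   pos0 = seq_along(profile$plus) - 1L,
                   plus_weight = profile$plus,
                   minus_weight = profile$minus)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write stranded coverage as TSV
#'
#' One row per position: reference, pos0, plus, minus.
#'
#' @param cov coverage list as returned by [strandedCoverage()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeCoverage <- function(cov, path) {
  df <- do.call(rbind, lapply(names(cov), function(nm) {
    data.frame(reference = nm, pos0 = seq_along(cov[[nm]]$plus) - 1L,
               plus = cov[[nm]]$plus, minus = cov[[nm]]$minus)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
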