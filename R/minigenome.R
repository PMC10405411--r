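#' Default minigenome specification
#'
#' A two-chromosome synthetic genome carrying every locus archetype the
#' antisense classifier must recognize:
#' \itemize{
#'   \item two tandem sense/antisense pairs (CUG1/ANC1, CUG2/ANC2) whose
#'     members overlap on opposite strands over 700 nt, modelled on the
#'     CUP1-1/RUF5-1 and CUP1-2/RUF5-2 tandems;
#'   \item one convergent pair (CYCL1/UTRL1) separated by a 150-nt
#'     intergenic gap bridged by transcriptional readthrough, modelled on
#'     CYC1/UTR1;
#'   \item one gene with unannotated antisense transcription (HAV1,
#'     hidden fraction 0.2), modelled on ICL1;
#'   \item a retroelement-like repeat present in three identical copies
#'     (TYR1-3), modelled on Ty1;
#'   \item three neutral single-stranded genes (PLN1-3).
#' }
#'
#' @return A \linkS4class{MinigenomeSpec}.
#' @examples
#' defaultMinigenomeSpec()
#' @export
defaultMinigenomeSpec <- function() {
  chrom <- c(chrA = 12000L, chrB = 8000L)
  g <- GRanges(
    seqnames = c(rep("chrA", 9), rep("chrB", 4)),
    ranges = IRanges(
      start = c(501, 801, 2501, 2801, 4501, 5651, 7501, 9001, 10201,
                501, 2501, 4501, 6001),
      end   = c(1500, 1800, 3500, 3800, 5500, 6650, 8500, 9800, 11000,
                1500, 3500, 5500, 6800)
    ),
    strand = c("+", "-", "+", "-", "+", "-", "+", "+", "-",
               "+", "+", "+", "+")
  )
  mcols(g)$gene_id <- c("CUG1", "ANC1", "CUG2", "ANC2", "CYCL1", "UTRL1",
                        "HAV1", "PLN1", "PLN2", "TYR1", "TYR2", "TYR3",
                        "PLN3")
  mcols(g)$class <- c("antisense_pair_member", "antisense_pair_member",
                      "antisense_pair_member", "antisense_pair_member",
                      "readthrough_member", "readthrough_member",
                      "hidden_antisense", "plain", "plain",
                      "repeat", "repeat", "repeat", "plain")
  mcols(g)$baseline_expression <- c(3, 2, 3, 2, 4, 4, 3, 1, 2, 2, 2, 2, 1.5)
  mcols(g)$hidden_antisense_fraction <- c(0, 0, 0, 0, 0, 0, 0.2, 0, 0,
                                          0, 0, 0, 0)
  MinigenomeSpec(chrom, g)
}

#' Build the chromosome sequences of a minigenome
#'
#' Generates random chromosome sequences for a \linkS4class{MinigenomeSpec}
#' and plants one shared sequence into all repeat-class gene intervals so
#' that the repeat element is truly multicopy. The result is byte-identical
#' for identical spec and seed.
#'
#' @param spec a \linkS4class{MinigenomeSpec}.
#' @param seed integer seed.
#' @return A \linkS4class{Minigenome}.
#' @examples
#' mg <- buildMinigenome(defaultMinigenomeSpec(), seed = 1)
#' genomeSequences(mg)
#' @export
buildMinigenome <- function(spec, seed = 1L) {
  validObject(spec)
  set.seed(seed)
  chrom <- spec@chromosomes
  seqs <- vapply(chrom, .randomDna, character(1))
  g <- spec@genes
  cls <- mcols(g)$class
  rep_idx <- which(cls == "repeat")
  if (length(rep_idx) >= 2L) {
    unit <- .randomDna(width(g)[rep_idx[1]])
    for (i in rep_idx) {
      nm <- as.character(seqnames(g))[i]
      substr(seqs[[nm]], start(g)[i], end(g)[i]) <- unit
    }
  }
  new("Minigenome", genome = DNAStringSet(seqs), genes = g,
      chromosomes = chrom)
}

#' Write reference sequences as FASTA
#'
#' @param x a \linkS4class{Minigenome}, [Biostrings::DNAStringSet], or a
#'   named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeReference <- function(x, path) {
  if (is(x, "Minigenome")) x <- x@genome
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readReference <- function(path) {
  x <- readDNAStringSet(path, format = "fasta")
  # keep only the identifier token of the description line
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  x
}

#' Write gene annotation as GFF3
#'
#' Records are written 1-based inclusive as GFF3 requires; an internal
#' 0-based half-open interval `[10, 20)` appears in the file as `11..20`.
#'
#' @param x a \linkS4class{Minigenome}, \linkS4class{MinigenomeSpec} or a
#'   `GRanges` with the gene metadata columns.
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(x, path) {
  g <- if (is(x, "GRanges")) x else x@genes
  out <- g
  mcols(out)$type <- "gene"
  mcols(out)$ID <- mcols(g)$gene_id
  mcols(out)$source <- "dicerscope"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' @param path GFF3 path.
#' @return A `GRanges` with the package's gene metadata columns restored.
#' @export
readAnnotation <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  mc <- mcols(g)
  keep <- intersect(c("gene_id", "class", "baseline_expression",
                      "hidden_antisense_fraction"), colnames(mc))
  out <- GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g))
  for (k in keep) mcols(out)[[k]] <- mc[[k]]
  if (!is.null(mcols(out)$baseline_expression))
    mcols(out)$baseline_expression <- as.numeric(mcols(out)$baseline_expression)
  if (!is.null(mcols(out)$hidden_antisense_fraction))
    mcols(out)$hidden_antisense_fraction <-
      as.numeric(mcols(out)$hidden_antisense_fraction)
  out
}
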