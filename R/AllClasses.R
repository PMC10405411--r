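#' @include utils.R
NULL

## ---------------------------------------------------------------- DicerModel

#' Generative model of Dicer processing
#'
#' `DicerModel` bundles the parameters that describe how a Dicer-like
#' enzyme converts a double-stranded substrate into small RNA duplexes:
#' the product size distribution over 20/21/22 nt, the fixed 2-nt 3'
#' overhang of RNase III products, the probability that a product is drawn
#' from the loop-permissive cut distribution (`loopLeak`), the probability
#' of sequencing the (+)-sense strand of a duplex (`strandEmission`), and
#' the fraction of library reads that are non-Dicer degradation background
#' (`backgroundFraction`, lengths uniform on 17-24 nt).
#'
#' The default size weights (0.1/0.6/0.3 for 20/21/22 nt) reproduce the
#' observed preponderance of 21-nt products with 22-nt products second.
#'
#' @slot sizeWeights named numeric over sizes "20", "21", "22"; sums to 1.
#' @slot overhang integer; always 2 for Dicer products.
#' @slot loopLeak numeric in [0, 1].
#' @slot strandEmission numeric in [0, 1].
#' @slot backgroundFraction numeric in [0, 1].
#' @name DicerModel-class
#' @rdname DicerModel
#' @exportClass DicerModel
setClass("DicerModel",
  representation(
    sizeWeights = "numeric",
    overhang = "integer",
    loopLeak = "numeric",
    strandEmission = "numeric",
    backgroundFraction = "numeric"
  )
)

setValidity("DicerModel", function(object) {
  msg <- character(0)
  w <- object@sizeWeights
  if (!all(names(w) %in% c("20", "21", "22")) || is.null(names(w)))
    msg <- c(msg, "sizeWeights must be named with sizes 20, 21, 22")
  if (any(w < 0)) msg <- c(msg, "sizeWeights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) msg <- c(msg, "sizeWeights must sum to 1 (tol 1e-9)")
  if (object@overhang != 2L) msg <- c(msg, "overhang must be 2 nt")
  for (s in c("loopLeak", "strandEmission", "backgroundFraction")) {
    v <- slot(object, s)
    if (length(v) != 1L || v < 0 || v > 1) msg <- c(msg, paste(s, "must be in [0,1]"))
  }
  if (length(msg)) msg else TRUE
})

#' @param sizeWeights named numeric of product-size probabilities.
#' @param loopLeak,strandEmission,backgroundFraction see slots.
#' @return `DicerModel()` returns a validated \linkS4class{DicerModel}.
#' @examples
#' DicerModel()
#' DicerModel(sizeWeights = c(`20` = 0.1, `21` = 0.6, `22` = 0.3))
#' @rdname DicerModel
#' @export
DicerModel <- function(sizeWeights = c(`20` = 0.1, `21` = 0.6, `22` = 0.3),
                       loopLeak = 0, strandEmission = 0.5,
                       backgroundFraction = 0.3) {
  new("DicerModel", sizeWeights = sizeWeights, overhang = 2L,
      loopLeak = loopLeak, strandEmission = strandEmission,
      backgroundFraction = backgroundFraction)
}

setMethod("show", "DicerModel", function(object) {
  w <- object@sizeWeights
  cat("DicerModel\n")
  cat("  size weights:",
      paste(sprintf("%s nt: %.3g", names(w), w), collapse = ", "), "\n")
  cat(sprintf("  3' overhang: %d nt | loop leak: %.3g | strand emission: %.3g | background: %.3g\n",
              object@overhang, object@loopLeak, object@strandEmission,
              object@backgroundFraction))
})

#' Accessors for DicerModel parameters
#' @param object a \linkS4class{DicerModel}.
#' @return `sizeWeights()` the named weight vector; `backgroundFraction()`
#'   the background read fraction.
#' @rdname DicerModel
#' @export
sizeWeights <- function(object) object@sizeWeights

#' @rdname DicerModel
#' @export
backgroundFraction <- function(object) object@backgroundFraction

## ---------------------------------------------------------- HairpinConstruct

#' Inverted-repeat hairpin transcript
#'
#' Sequence model of an inducible inverted-repeat ("strong silencing
#' construct") transcript: a 5' arm, a single-stranded intron loop, and the
#' exact reverse complement of the arm. Folding the transcript back on
#' itself pairs arm positions i with positions (2*arm + loop) - 1 - i,
#' yielding a perfect double-stranded stem interrupted by the loop. With
#' a 275-nt arm and the 79-nt intron loop the transcript is 629 nt.
#'
#' @slot armLength,loopLength integer lengths in nt.
#' @slot sequence a [Biostrings::DNAString] of length 2*arm + loop.
#' @name HairpinConstruct-class
#' @rdname HairpinConstruct
#' @exportClass HairpinConstruct
setClass("HairpinConstruct",
  representation(
    armLength = "integer",
    loopLength = "integer",
    sequence = "DNAString"
  )
)

setValidity("HairpinConstruct", function(object) {
  a <- object@armLength; l <- object@loopLength
  msg <- character(0)
  if (a < 0L) msg <- c(msg, "armLength must be >= 0")
  if (l < 1L) msg <- c(msg, "loopLength must be >= 1")
  if (length(object@sequence) != 2L * a + l)
    msg <- c(msg, "transcript length must equal 2*arm + loop")
  if (a > 0L) {
    s <- as.character(object@sequence)
    arm1 <- substr(s, 1L, a)
    arm2 <- substr(s, a + l + 1L, 2L * a + l)
    if (.revcomp(arm1) != arm2)
      msg <- c(msg, "second arm must be the reverse complement of the first")
  }
  if (length(msg)) msg else TRUE
})

#' Build a hairpin construct
#'
#' @param armLength arm length in nt (>= 0).
#' @param loopLength loop length in nt (>= 1).
#' @param seed integer seed for the random arm and loop sequences.
#' @return `buildHairpin()` returns a \linkS4class{HairpinConstruct}.
#' @examples
#' hp <- buildHairpin(275, 79, seed = 1)
#' length(transcriptSequence(hp))  # 629
#' stemIntervals(hp)
#' @rdname HairpinConstruct
#' @export
buildHairpin <- function(armLength, loopLength, seed = 1L) {
  if (armLength < 0 || loopLength < 1)
    stop("armLength must be >= 0 and loopLength >= 1")
  armLength <- as.integer(armLength); loopLength <- as.integer(loopLength)
  set.seed(seed)
  arm <- .randomDna(armLength)
  loop <- .randomDna(loopLength)
  tr <- paste0(arm, loop, if (armLength > 0L) .revcomp(arm) else "")
  new("HairpinConstruct", armLength = armLength, loopLength = loopLength,
      sequence = DNAString(tr))
}

#' @param object,x a \linkS4class{HairpinConstruct}.
#' @return `armLength()`/`loopLength()` integer lengths;
#'   `transcriptSequence()` the [Biostrings::DNAString];
#'   `stemIntervals()` an [IRanges::IRanges] with the two stem intervals
#'   (1-based inclusive; equivalently `[0, arm)` and `[arm+loop, 2*arm+loop)`
#'   0-based half-open); `loopInterval()` the loop interval.
#' @rdname HairpinConstruct
#' @export
armLength <- function(object) object@armLength

#' @rdname HairpinConstruct
#' @export
loopLength <- function(object) object@loopLength

#' @rdname HairpinConstruct
#' @export
transcriptSequence <- function(object) object@sequence

#' @rdname HairpinConstruct
#' @export
stemIntervals <- function(object) {
  a <- object@armLength; l <- object@loopLength
  if (a == 0L) return(IRanges())
  IRanges(start = c(1L, a + l + 1L), end = c(a, 2L * a + l))
}

#' @rdname HairpinConstruct
#' @export
loopInterval <- function(object) {
  a <- object@armLength; l <- object@loopLength
  IRanges(start = a + 1L, end = a + l)
}

setMethod("show", "HairpinConstruct", function(object) {
  cat(sprintf("HairpinConstruct: %d-nt transcript (arm %d nt, loop %d nt)\n",
              length(object@sequence), object@armLength, object@loopLength))
})

## ------------------------------------------------------------- RepliconModel

#' Replicase-assisted defective-interfering replicon
#'
#' Model of a subviral DI-RNA replicon amplified by a viral replicase in
#' membrane-associated complexes. Replication introduces single-nucleotide
#' variants at `perSiteMutationRate` per site per molecule (3% in the
#' CymRSV DI-3 system), and only a small fraction `accessibility` of the
#' molecules is exposed to Dicer -- the replication niches shield the rest.
#' The default sequence length is 477 nt, the length of DI-3.
#'
#' @slot sequence a [Biostrings::DNAString] replicon sequence.
#' @slot perSiteMutationRate numeric in [0, 1].
#' @slot accessibility numeric in [0, 1].
#' @name RepliconModel-class
#' @rdname RepliconModel
#' @exportClass RepliconModel
setClass("RepliconModel",
  representation(
    sequence = "DNAString",
    perSiteMutationRate = "numeric",
    accessibility = "numeric"
  )
)

setValidity("RepliconModel", function(object) {
  msg <- character(0)
  for (s in c("perSiteMutationRate", "accessibility")) {
    v <- slot(object, s)
    if (length(v) != 1L || v < 0 || v > 1) msg <- c(msg, paste(s, "must be in [0,1]"))
  }
  if (length(object@sequence) < 1L) msg <- c(msg, "sequence must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @param length replicon length in nt used when `sequence` is NULL.
#' @param perSiteMutationRate,accessibility see slots.
#' @param sequence optional explicit sequence (character or DNAString).
#' @param seed integer seed for the random default sequence.
#' @return `RepliconModel()` returns a validated \linkS4class{RepliconModel}.
#' @examples
#' RepliconModel(seed = 2)
#' @rdname RepliconModel
#' @export
RepliconModel <- function(length = 477L, perSiteMutationRate = 0.03,
                          accessibility = 0.01, sequence = NULL, seed = 1L) {
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- .randomDna(as.integer(length))
  }
  new("RepliconModel", sequence = DNAString(as.character(sequence)),
      perSiteMutationRate = perSiteMutationRate,
      accessibility = accessibility)
}

setMethod("show", "RepliconModel", function(object) {
  cat(sprintf("RepliconModel: %d nt | per-site mutation rate %.3g | Dicer accessibility %.3g\n",
              length(object@sequence), object@perSiteMutationRate,
              object@accessibility))
})

## ------------------------------------------------------------------- ReadSet

#' A set of simulated reads with ground-truth provenance
#'
#' Container pairing simulated read sequences with the table that records
#' where each read truly came from: generating substrate (chromosome,
#' "hairpin", "replicon" or a background decoy), 0-based half-open
#' coordinates on that substrate, strand of origin and the number of
#' replication mutations carried. The provenance is the ground truth that
#' downstream detection is tested against; it is never consulted by the
#' aligner or the classifiers.
#'
#' @slot reads a named [Biostrings::DNAStringSet].
#' @slot provenance a data.frame with columns read_id, substrate, start0,
#'   end0, strand, n_mutations (plus optional extras such as gene).
#' @name ReadSet-class
#' @rdname ReadSet
#' @exportClass ReadSet
setClass("ReadSet",
  representation(reads = "DNAStringSet", provenance = "data.frame")
)

setValidity("ReadSet", function(object) {
  msg <- character(0)
  req <- c("read_id", "substrate", "start0", "end0", "strand", "n_mutations")
  if (!all(req %in% colnames(object@provenance)))
    msg <- c(msg, paste("provenance must have columns:", paste(req, collapse = ", ")))
  else {
    ids <- names(object@reads)
    if (is.null(ids) && length(object@reads) > 0L)
      msg <- c(msg, "reads must be named")
    else if (!all(ids %in% object@provenance$read_id))
      msg <- c(msg, "provenance must cover every read id")
  }
  if (length(msg)) msg else TRUE
})

#' @param reads named DNAStringSet (or character vector) of read sequences.
#' @param provenance provenance data.frame (see slots).
#' @return `ReadSet()` returns a validated \linkS4class{ReadSet}.
#' @rdname ReadSet
#' @export
ReadSet <- function(reads = DNAStringSet(), provenance = .emptyProvenance()) {
  if (is.character(reads)) reads <- DNAStringSet(reads)
  new("ReadSet", reads = reads, provenance = provenance)
}

.emptyProvenance <- function() {
  data.frame(read_id = character(0), substrate = character(0),
             start0 = integer(0), end0 = integer(0), strand = character(0),
             n_mutations = integer(0), stringsAsFactors = FALSE)
}

#' @param object,x a \linkS4class{ReadSet}.
#' @return `reads()` the DNAStringSet; `provenance()` the data.frame.
#' @rdname ReadSet
#' @export
reads <- function(object) object@reads

#' @rdname ReadSet
#' @export
provenance <- function(object) object@provenance

#' @rdname ReadSet
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

setMethod("show", "ReadSet", function(object) {
  n <- length(object@reads)
  cat(sprintf("ReadSet: %d reads", n))
  if (n > 0L) {
    w <- range(BiocGenerics::width(object@reads))
    cat(sprintf(" (%d-%d nt) from %d substrate(s)", w[1], w[2],
                length(unique(object@provenance$substrate))))
  }
  cat("\n")
})

#' Concatenate read sets
#'
#' @param ... \linkS4class{ReadSet} objects.
#' @return A single \linkS4class{ReadSet}; read ids must be unique overall.
#' @export
combineReadSets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, length, 1L) > 0L |
                 vapply(sets, function(s) nrow(s@provenance), 1L) > 0L]
  if (!length(sets)) return(ReadSet())
  rd <- do.call(c, lapply(sets, function(s) s@reads))
  pv <- do.call(rbind, lapply(sets, function(s) s@provenance[
    intersect(colnames(.emptyProvenance()), colnames(s@provenance))]))
  if (anyDuplicated(names(rd))) stop("read ids must be unique across sets")
  rownames(pv) <- NULL
  ReadSet(rd, pv)
}

## ------------------------------------------------------------ MinigenomeSpec

.geneClasses <- c("plain", "antisense_pair_member", "readthrough_member",
                  "hidden_antisense", "repeat")

#' Specification of a synthetic minigenome
#'
#' Describes chromosomes and gene models for a small synthetic genome that
#' contains every locus archetype the antisense analysis must recognize:
#' tandem gene/antisense pairs (as in the CUP1/RUF5 tandems), a convergent
#' gene pair joined by transcriptional readthrough across a short
#' intergenic gap (as in CYC1/UTR1), a gene with unannotated antisense
#' transcription (as in ICL1), a multicopy retroelement-like repeat, and
#' neutral single-stranded genes.
#'
#' @slot chromosomes named integer vector of chromosome lengths (nt).
#' @slot genes a [GenomicRanges::GRanges] with metadata columns gene_id,
#'   class (one of plain, antisense_pair_member, readthrough_member,
#'   hidden_antisense, repeat), baseline_expression (reads per transcript
#'   copy) and hidden_antisense_fraction (in [0,1], positive only for
#'   hidden_antisense genes).
#' @name MinigenomeSpec-class
#' @rdname MinigenomeSpec
#' @exportClass MinigenomeSpec
setClass("MinigenomeSpec",
  representation(chromosomes = "integer", genes = "GRanges")
)

setValidity("MinigenomeSpec", function(object) {
  msg <- character(0)
  chrom <- object@chromosomes
  g <- object@genes
  mc <- mcols(g)
  req <- c("gene_id", "class", "baseline_expression", "hidden_antisense_fraction")
  if (!all(req %in% colnames(mc)))
    return(paste("genes must carry metadata columns:", paste(req, collapse = ", ")))
  if (is.null(names(chrom)) || any(names(chrom) == ""))
    msg <- c(msg, "chromosomes must be named")
  if (anyDuplicated(mc$gene_id)) msg <- c(msg, "gene ids must be unique")
  if (!all(mc$class %in% .geneClasses))
    msg <- c(msg, paste("gene class must be one of:", paste(.geneClasses, collapse = ", ")))
  if (any(mc$baseline_expression < 0))
    msg <- c(msg, "baseline_expression must be non-negative")
  if (any(mc$hidden_antisense_fraction < 0 | mc$hidden_antisense_fraction > 1))
    msg <- c(msg, "hidden_antisense_fraction must be in [0,1]")
  if (any(mc$hidden_antisense_fraction > 0 & mc$class != "hidden_antisense"))
    msg <- c(msg, "hidden_antisense_fraction > 0 only allowed for hidden_antisense genes")
  # chromosome bounds
  if (!all(as.character(seqnames(g)) %in% names(chrom)))
    msg <- c(msg, "every gene must lie on a declared chromosome")
  else {
    lim <- chrom[as.character(seqnames(g))]
    if (any(start(g) < 1L) || any(end(g) > lim))
      msg <- c(msg, "gene interval exceeds chromosome bounds")
  }
  # same-strand overlap between distinct genes is rejected
  for (st in c("+", "-")) {
    gs <- g[as.character(strand(g)) == st]
    if (length(gs) > 1L) {
      ov <- findOverlaps(gs, gs)
      if (any(queryHits(ov) != subjectHits(ov)))
        msg <- c(msg, "overlapping same-strand genes are not allowed")
    }
  }
  # required locus classes
  cls <- mc$class
  if (sum(cls == "antisense_pair_member") < 2L)
    msg <- c(msg, "need at least one tandem sense/antisense pair")
  if (sum(cls == "readthrough_member") < 2L)
    msg <- c(msg, "need at least one convergent readthrough pair")
  if (sum(cls == "hidden_antisense") < 1L)
    msg <- c(msg, "need at least one hidden-antisense gene")
  if (sum(cls == "repeat") < 2L)
    msg <- c(msg, "need a multicopy repeat element (>= 2 copies)")
  if (sum(cls == "plain") < 3L)
    msg <- c(msg, "need at least three neutral (plain) genes")
  if (sum(cls == "repeat") >= 2L &&
      length(unique(width(g[cls == "repeat"]))) != 1L)
    msg <- c(msg, "repeat copies must share one width")
  if (length(msg)) msg else TRUE
})

#' @param chromosomes,genes see slots.
#' @return `MinigenomeSpec()` returns a validated \linkS4class{MinigenomeSpec}.
#' @rdname MinigenomeSpec
#' @export
MinigenomeSpec <- function(chromosomes, genes) {
  new("MinigenomeSpec", chromosomes = chromosomes, genes = genes)
}

setMethod("show", "MinigenomeSpec", function(object) {
  cat(sprintf("MinigenomeSpec: %d chromosome(s), %d gene(s)\n",
              length(object@chromosomes), length(object@genes)))
  print(table(mcols(object@genes)$class))
})

#' @rdname MinigenomeSpec
#' @param object a \linkS4class{MinigenomeSpec} or \linkS4class{Minigenome}.
#' @export
chromosomeLengths <- function(object) object@chromosomes

#' @rdname MinigenomeSpec
#' @export
genes <- function(object) {
  if (is(object, "Minigenome")) object@genes else object@genes
}

## ---------------------------------------------------------------- Minigenome

#' A realized synthetic minigenome
#'
#' The output of [buildMinigenome()]: chromosome sequences plus the gene
#' annotation carried over from the \linkS4class{MinigenomeSpec}.
#'
#' @slot genome a named [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes the annotated [GenomicRanges::GRanges].
#' @slot chromosomes named integer chromosome lengths.
#' @name Minigenome-class
#' @rdname Minigenome
#' @exportClass Minigenome
setClass("Minigenome",
  representation(genome = "DNAStringSet", genes = "GRanges",
                 chromosomes = "integer")
)

setMethod("show", "Minigenome", function(object) {
  cat(sprintf("Minigenome: %d chromosome(s) (%d nt total), %d gene(s)\n",
              length(object@genome), sum(BiocGenerics::width(object@genome)),
              length(object@genes)))
})

#' @rdname Minigenome
#' @param object a \linkS4class{Minigenome}.
#' @export
genomeSequences <- function(object) object@genome
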