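#' Simulate Dicer small RNA duplex production
#'
#' Draws sRNA duplexes from a double-stranded substrate under a
#' \linkS4class{DicerModel} and emits one sequenced read per duplex. Each
#' duplex has guide and passenger strands of equal size k in \{20, 21, 22\}
#' offset by 2 nt so that both 3' ends protrude exactly 2 nt, the chemical
#' hallmark of RNase III products. Cut positions are uniform over the
#' double-stranded region; on a hairpin substrate, a `loopLeak` fraction of
#' the draws instead uses the loop-permissive distribution in which
#' products may overlap the single-stranded loop. The sequenced strand of
#' each duplex is chosen with probability `strandEmission` (guide, i.e. the
#' (+)-sense strand, versus passenger). A `backgroundFraction` share of the
#' emitted library consists of non-Dicer degradation fragments with lengths
#' uniform on 17-24 nt, drawn from `backgroundPool` (a decoy pool of
#' cellular transcripts is generated when none is supplied).
#'
#' For a \linkS4class{HairpinConstruct} substrate both duplex strands are
#' substrings of the (+) transcript (one per arm, paired through the fold);
#' for a plain sequence substrate ("duplex region") the guide is a
#' (+)-strand substring and the passenger the reverse complement of the
#' 2-nt-shifted window.
#'
#' @param substrate a \linkS4class{HairpinConstruct}, or a character /
#'   [Biostrings::DNAString] giving the (+) strand of a fully
#'   double-stranded region.
#' @param model a \linkS4class{DicerModel}.
#' @param n total number of reads to emit (Dicer products + background).
#' @param seed integer seed.
#' @param backgroundPool optional named character vector /
#'   [Biostrings::DNAStringSet] of transcripts degradation reads are drawn
#'   from.
#' @param idPrefix prefix for read identifiers.
#' @param substrateName substrate label recorded in provenance.
#' @return A list with elements `duplexes` (data.frame: substrate, size,
#'   guideStart, guideEnd, passengerStart, passengerEnd, overlapsLoop;
#'   coordinates 0-based half-open on the substrate, passenger coordinates
#'   on the (+) strand it covers) and `reads` (a \linkS4class{ReadSet}).
#' @examples
#' hp <- buildHairpin(275, 79, seed = 1)
#' sim <- simulateDicerProducts(hp, DicerModel(backgroundFraction = 0),
#'                              n = 100, seed = 2)
#' head(sim$duplexes)
#' @export
setGeneric("simulateDicerProducts",
  function(substrate, model, n, seed = 1L, backgroundPool = NULL,
           idPrefix = "sr", substrateName = NULL)
    standardGeneric("simulateDicerProducts"))

.sampleSizes <- function(model, n) {
  sizes <- as.integer(names(model@sizeWeights))
  if (n == 0L) return(integer(0))
  sizes[sample.int(length(sizes), n, replace = TRUE,
                   prob = model@sizeWeights)]
}

# background degradation reads: uniform over pool transcripts, lengths 17-24
.backgroundReads <- function(pool, n, idPrefix) {
  if (n == 0L) return(list(seq = character(0), prov = .emptyProvenance()))
  poolChar <- if (is.character(pool)) pool else as.character(pool)
  if (is.null(names(poolChar)))
    names(poolChar) <- sprintf("bg%02d", seq_along(poolChar))
  lens <- nchar(poolChar)
  len <- sample(17:24, n, replace = TRUE)
  ti <- sample(seq_along(poolChar), n, replace = TRUE, prob = lens)
  maxStart <- lens[ti] - len
  if (any(maxStart < 0)) stop("background pool transcripts shorter than 24 nt")
  s0 <- floor(runif(n) * (maxStart + 1))
  seqs <- substring(poolChar[ti], s0 + 1L, s0 + len)
  prov <- data.frame(
    read_id = sprintf("%s_bg%07d", idPrefix, seq_len(n)),
    substrate = names(poolChar)[ti],
    start0 = as.integer(s0), end0 = as.integer(s0 + len),
    strand = "+", n_mutations = 0L, stringsAsFactors = FALSE)
  list(seq = unname(seqs), prov = prov)
}

.decoyPool <- function(seed, nTranscripts = 20L, len = 1000L) {
  set.seed(seed)
  setNames(vapply(seq_len(nTranscripts), function(i) .randomDna(len),
                  character(1)),
           sprintf("decoy%02d", seq_len(nTranscripts)))
}

.assembleReads <- function(dicerSeq, dicerProv, model, nBg, backgroundPool,
                           seed, idPrefix) {
  if (nBg > 0L) {
    if (is.null(backgroundPool))
      backgroundPool <- .decoyPool(deriveSeed(seed, 7L))
    bg <- .backgroundReads(backgroundPool, nBg, idPrefix)
  } else {
    bg <- list(seq = character(0), prov = .emptyProvenance())
  }
  seqs <- c(dicerSeq, bg$seq)
  prov <- rbind(dicerProv, bg$prov)
  rd <- DNAStringSet(seqs)
  names(rd) <- prov$read_id
  ReadSet(rd, prov)
}

#' @rdname simulateDicerProducts
#' @export
setMethod("simulateDicerProducts", "HairpinConstruct",
  function(substrate, model, n, seed = 1L, backgroundPool = NULL,
           idPrefix = "hp", substrateName = "hairpin") {
    stopifnot(n >= 0)
    n <- as.integer(n)
    a <- substrate@armLength; l <- substrate@loopLength
    len <- 2L * a + l
    tr <- as.character(substrate@sequence)
    set.seed(seed)
    nBg <- rbinom(1L, n, model@backgroundFraction)
    nD <- n - nBg
    if (nD == 0L) {
      duplexes <- data.frame(substrate = character(0), size = integer(0),
                             guideStart = integer(0), guideEnd = integer(0),
                             passengerStart = integer(0),
                             passengerEnd = integer(0),
                             duplexType = character(0),
                             overlapsLoop = logical(0),
                             stringsAsFactors = FALSE)
      return(list(duplexes = duplexes,
                  reads = .assembleReads(character(0), .emptyProvenance(),
                                         model, nBg, backgroundPool, seed,
                                         idPrefix)))
    }
    sizes <- .sampleSizes(model, nD)
    minK <- min(sizes)
    if (a < minK + 2L)
      stop("substrate has no usable double-stranded region")
    permissive <- runif(nD) < model@loopLeak
    k <- sizes
    # stem-constrained cuts along the pairing axis: p uniform on [2, a-k].
    # The guide occupies transcript [p, p+k) on the 5' arm; through the
    # fold (i pairs with len-1-i) the passenger occupies
    # [len-p-k+2, len-p+2) on the 3' arm, leaving both 3' ends 2 nt free.
    nStem <- a - k - 1L
    p <- 2L + as.integer(floor(runif(nD) * nStem))
    guideStart <- p
    guideEnd <- p + k
    passStart <- len - p - k + 2L
    passEnd <- len - p + 2L
    passStrand <- rep("+", nD)
    duplexType <- rep("stem_pairing", nD)
    # loop-permissive cuts: the construct is treated as one linear duplex
    # (loop processed like stem); the passenger is the reverse complement
    # of the 2-nt-shifted window, p uniform on [2, len-k]
    if (any(permissive)) {
      idx <- which(permissive)
      p2 <- 2L + as.integer(floor(runif(length(idx)) * (len - k[idx] - 1L)))
      guideStart[idx] <- p2
      guideEnd[idx] <- p2 + k[idx]
      passStart[idx] <- p2 - 2L
      passEnd[idx] <- p2 + k[idx] - 2L
      passStrand[idx] <- "-"
      duplexType[idx] <- "linear"
    }
    overlapsLoop <- (guideStart < a + l & guideEnd > a) |
                    (passStart < a + l & passEnd > a)
    emitGuide <- runif(nD) < model@strandEmission
    rs <- ifelse(emitGuide, guideStart, passStart)
    re <- ifelse(emitGuide, guideEnd, passEnd)
    rstrand <- ifelse(emitGuide, "+", passStrand)
    plus <- substring(tr, rs + 1L, re)
    seqs <- ifelse(rstrand == "+", plus, .revcomp(plus))
    prov <- data.frame(
      read_id = sprintf("%s_%07d", idPrefix, seq_len(nD)),
      substrate = substrateName,
      start0 = as.integer(rs), end0 = as.integer(re),
      strand = rstrand, n_mutations = 0L, stringsAsFactors = FALSE)
    duplexes <- data.frame(
      substrate = rep(substrateName, nD), size = k,
      guideStart = guideStart, guideEnd = guideEnd,
      passengerStart = passStart, passengerEnd = passEnd,
      duplexType = duplexType,
      overlapsLoop = overlapsLoop, stringsAsFactors = FALSE)
    list(duplexes = duplexes,
         reads = .assembleReads(unname(seqs), prov, model, nBg,
                                backgroundPool, seed, idPrefix))
  })

# shared implementation for plain duplex regions
.simulateRegion <- function(regionChar, model, n, seed, backgroundPool,
                            idPrefix, substrateName) {
  stopifnot(n >= 0)
  n <- as.integer(n)
  L <- nchar(regionChar)
  set.seed(seed)
  nBg <- rbinom(1L, n, model@backgroundFraction)
  nD <- n - nBg
  if (nD == 0L) {
    duplexes <- data.frame(substrate = character(0), size = integer(0),
                           guideStart = integer(0), guideEnd = integer(0),
                           passengerStart = integer(0),
                           passengerEnd = integer(0),
                           duplexType = character(0),
                           overlapsLoop = logical(0),
                           stringsAsFactors = FALSE)
    return(list(duplexes = duplexes,
                reads = .assembleReads(character(0), .emptyProvenance(),
                                       model, nBg, backgroundPool, seed,
                                       idPrefix)))
  }
  sizes <- .sampleSizes(model, nD)
  if (L < max(sizes) + 3L)
    stop("substrate has no usable double-stranded region")
  k <- sizes
  # cut positions: p uniform on [2, L - k]; passenger occupies [p-2, p+k-2)
  p <- 2L + as.integer(floor(runif(nD) * (L - k - 1L)))
  guideStart <- p; guideEnd <- p + k
  passStart <- p - 2L; passEnd <- p + k - 2L
  emitGuide <- runif(nD) < model@strandEmission
  rs <- ifelse(emitGuide, guideStart, passStart)
  re <- ifelse(emitGuide, guideEnd, passEnd)
  plus <- substring(regionChar, rs + 1L, re)
  seqs <- ifelse(emitGuide, plus, .revcomp(plus))
  prov <- data.frame(
    read_id = sprintf("%s_%07d", idPrefix, seq_len(nD)),
    substrate = substrateName,
    start0 = as.integer(rs), end0 = as.integer(re),
    strand = ifelse(emitGuide, "+", "-"),
    n_mutations = 0L, stringsAsFactors = FALSE)
  duplexes <- data.frame(
    substrate = rep(substrateName, nD), size = k,
    guideStart = guideStart, guideEnd = guideEnd,
    passengerStart = passStart, passengerEnd = passEnd,
    duplexType = rep("linear", nD),
    overlapsLoop = rep(NA, nD), stringsAsFactors = FALSE)
  list(duplexes = duplexes,
       reads = .assembleReads(unname(seqs), prov, model, nBg,
                              backgroundPool, seed, idPrefix))
}

#' @rdname simulateDicerProducts
#' @export
setMethod("simulateDicerProducts", "character",
  function(substrate, model, n, seed = 1L, backgroundPool = NULL,
           idPrefix = "ds", substrateName = "region") {
    .simulateRegion(substrate, model, n, seed, backgroundPool, idPrefix,
                    substrateName)
  })

#' @rdname simulateDicerProducts
#' @export
setMethod("simulateDicerProducts", "DNAString",
  function(substrate, model, n, seed = 1L, backgroundPool = NULL,
           idPrefix = "ds", substrateName = "region") {
    .simulateRegion(as.character(substrate), model, n, seed, backgroundPool,
                    idPrefix, substrateName)
  })
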