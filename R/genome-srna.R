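#' Simulate the genomic sRNA library of a Dicer-expressing cell
#'
#' Identifies every double-stranded region of the minigenome that Dicer can
#' perceive and dices it with [simulateDicerProducts()]:
#' \itemize{
#'   \item the overlap interval of each annotated sense/antisense gene
#'     pair (perfect dsRNA from co-transcription);
#'   \item the readthrough window of each convergent gene pair: the
#'     intergenic gap plus `readthroughExtension` nt into both genes
#'     (dsRNA from mRNA elongation across the gap);
#'   \item the whole body of each gene with unannotated antisense
#'     transcription, at intensity proportional to its hidden fraction;
#'   \item each copy of the multicopy repeat element, up-weighted by
#'     `repeatBoost` to reproduce the massive retroelement-derived sRNA
#'     signal.
#' }
#' Reads are allocated to regions by a multinomial draw over region
#' intensities (expression of the weaker strand times region width). The
#' model's `backgroundFraction` of the library is sense-strand degradation
#' of expressed transcripts with lengths uniform on 17-24 nt.
#'
#' @param mg a \linkS4class{Minigenome}.
#' @param dicer a \linkS4class{DicerModel}.
#' @param nReads total sRNA reads to emit.
#' @param seed integer seed.
#' @param readthroughFraction weight factor of readthrough dsRNA relative
#'   to full co-transcription.
#' @param readthroughExtension nt the readthrough duplex reaches into each
#'   convergent gene.
#' @param repeatBoost intensity multiplier for repeat elements.
#' @return A \linkS4class{ReadSet}; provenance coordinates are genomic
#'   (0-based half-open, chromosome in `substrate`).
#' @examples
#' mg <- buildMinigenome(defaultMinigenomeSpec(), seed = 1)
#' rs <- simulateGenomeSrna(mg, DicerModel(), nReads = 2000, seed = 2)
#' rs
#' @export
simulateGenomeSrna <- function(mg, dicer, nReads, seed = 1L,
                               readthroughFraction = 0.3,
                               readthroughExtension = 150L,
                               repeatBoost = 10) {
  stopifnot(nReads >= 0)
  nReads <- as.integer(nReads)
  if (nReads == 0L) return(ReadSet())
  g <- mg@genes
  genomeChar <- as.character(mg@genome)
  ids <- mcols(g)$gene_id
  cls <- mcols(g)$class
  expr <- mcols(g)$baseline_expression
  chrom <- as.character(seqnames(g))
  gStrand <- as.character(strand(g))
  s0 <- start(g) - 1L; e0 <- end(g)

  regions <- list()
  addRegion <- function(chr, rs, re, weight, tag) {
    regions[[length(regions) + 1L]] <<- list(
      chrom = chr, start0 = as.integer(rs), end0 = as.integer(re),
      weight = weight, tag = tag)
  }
  # annotated antisense-pair overlaps
  pairIdx <- which(cls == "antisense_pair_member")
  if (length(pairIdx) > 1L) {
    gp <- g[pairIdx]
    ov <- findOverlaps(gp, gp, ignore.strand = TRUE)
    seen <- character(0)
    for (h in seq_along(ov)) {
      i <- queryHits(ov)[h]; j <- subjectHits(ov)[h]
      if (i >= j) next
      if (gStrand[pairIdx[i]] == gStrand[pairIdx[j]]) next
      key <- paste(sort(c(i, j)), collapse = "_")
      if (key %in% seen) next
      seen <- c(seen, key)
      rs <- max(s0[pairIdx[i]], s0[pairIdx[j]])
      re <- min(e0[pairIdx[i]], e0[pairIdx[j]])
      wgt <- min(expr[pairIdx[i]], expr[pairIdx[j]]) * (re - rs)
      addRegion(chrom[pairIdx[i]], rs, re, wgt,
                paste0("pair:", ids[pairIdx[i]], "/", ids[pairIdx[j]]))
    }
  }
  # convergent readthrough windows
  rtIdx <- which(cls == "readthrough_member" & gStrand == "+")
  for (i in rtIdx) {
    part <- which(cls == "readthrough_member" & chrom == chrom[i] &
                  gStrand == "-" & s0 >= e0[i])
    if (!length(part)) next
    j <- part[which.min(s0[part])]
    rs <- max(s0[i], e0[i] - readthroughExtension)
    re <- min(e0[j], s0[j] + readthroughExtension)
    wgt <- readthroughFraction * min(expr[i], expr[j]) * (re - rs)
    addRegion(chrom[i], rs, re, wgt,
              paste0("readthrough:", ids[i], "/", ids[j]))
  }
  # hidden antisense gene bodies
  for (i in which(cls == "hidden_antisense")) {
    frac <- mcols(g)$hidden_antisense_fraction[i]
    addRegion(chrom[i], s0[i], e0[i], expr[i] * frac * (e0[i] - s0[i]),
              paste0("hidden:", ids[i]))
  }
  # repeat copies
  for (i in which(cls == "repeat")) {
    addRegion(chrom[i], s0[i], e0[i], expr[i] * repeatBoost * (e0[i] - s0[i]),
              paste0("repeat:", ids[i]))
  }
  if (!length(regions)) stop("minigenome contains no double-stranded region")

  set.seed(seed)
  nBg <- rbinom(1L, nReads, dicer@backgroundFraction)
  nD <- nReads - nBg
  wgt <- vapply(regions, `[[`, numeric(1), "weight")
  alloc <- as.integer(stats::rmultinom(1L, nD, wgt))
  noBg <- DicerModel(sizeWeights = dicer@sizeWeights,
                     loopLeak = dicer@loopLeak,
                     strandEmission = dicer@strandEmission,
                     backgroundFraction = 0)
  parts <- vector("list", length(regions))
  for (r in seq_along(regions)) {
    if (alloc[r] == 0L) next
    reg <- regions[[r]]
    regSeq <- substring(genomeChar[[reg$chrom]], reg$start0 + 1L, reg$end0)
    sim <- .simulateRegion(regSeq, noBg, alloc[r],
                           seed = deriveSeed(seed, 100L + r),
                           backgroundPool = NULL,
                           idPrefix = sprintf("gs%02d", r),
                           substrateName = reg$chrom)
    pv <- sim$reads@provenance
    pv$start0 <- pv$start0 + reg$start0
    pv$end0 <- pv$end0 + reg$start0
    parts[[r]] <- list(seq = as.character(sim$reads@reads), prov = pv)
  }
  # background: sense-strand degradation of expressed transcripts
  if (nBg > 0L) {
    set.seed(deriveSeed(seed, 999L))
    w <- expr * width(g)
    gi <- sample(seq_along(g), nBg, replace = TRUE, prob = w)
    len <- sample(17:24, nBg, replace = TRUE)
    span <- (e0[gi] - s0[gi]) - len
    rs <- s0[gi] + as.integer(floor(runif(nBg) * (span + 1)))
    re <- rs + len
    plus <- substring(genomeChar[chrom[gi]], rs + 1L, re)
    seqs <- ifelse(gStrand[gi] == "+", plus, .revcomp(plus))
    parts[[length(parts) + 1L]] <- list(
      seq = unname(seqs),
      prov = data.frame(
        read_id = sprintf("gbg_%07d", seq_len(nBg)),
        substrate = chrom[gi], start0 = rs, end0 = re,
        strand = gStrand[gi], n_mutations = 0L, stringsAsFactors = FALSE))
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  seqs <- unlist(lapply(parts, `[[`, "seq"), use.names = FALSE)
  prov <- do.call(rbind, lapply(parts, function(p)
    p$prov[, colnames(.emptyProvenance())]))
  rownames(prov) <- NULL
  rd <- DNAStringSet(seqs)
  names(rd) <- prov$read_id
  ReadSet(rd, prov)
}
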