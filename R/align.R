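#' Trim 3' adapters from sRNA reads
#'
#' The leftmost exact occurrence of the adapter prefix (at least
#' `minAdapterMatch` nt, default 8) truncates the read; a terminal partial
#' adapter shorter than the prefix is left in place (reads here are
#' synthetic, so error-tolerant matching is unnecessary). Reads outside
#' `[minLen, maxLen]` after trimming are discarded, including untrimmable
#' full-length reads longer than `maxLen`.
#'
#' @param sequences character vector (or DNAStringSet) of raw reads.
#' @param adapter adapter sequence (>= `minAdapterMatch` nt).
#' @param minLen,maxLen length window kept after trimming.
#' @param minAdapterMatch minimum exact prefix match, nt.
#' @return Character vector of kept inserts, named like the input.
#' @examples
#' trimAdapter(c(r1 = paste0(strrep("A", 21), "TGGAATTCTCGG")),
#'             adapter = "TGGAATTCTCGGGTGCCAAGG")
#' @export
trimAdapter <- function(sequences, adapter, minLen = 17L, maxLen = 24L,
                        minAdapterMatch = 8L) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  if (nchar(adapter) < minAdapterMatch)
    stop("adapter must be at least ", minAdapterMatch, " nt")
  key <- substr(adapter, 1L, minAdapterMatch)
  pos <- regexpr(key, sequences, fixed = TRUE)
  out <- ifelse(pos > 0L, substr(sequences, 1L, pos - 1L), sequences)
  names(out) <- names(sequences)
  len <- nchar(out)
  out[len >= minLen & len <= maxLen]
}

# ---------------------------------------------------------------- alignment

# strand-resolved text representation of the references
.refTexts <- function(references) {
  refChar <- if (is.character(references)) references
             else as.character(references)
  if (length(refChar) == 0L) stop("empty reference set")
  if (is.null(names(refChar)) || any(names(refChar) == ""))
    stop("references must be named")
  list(plus = refChar, minus = .revcomp(refChar), len = nchar(refChar))
}

# k-mer lookup over both strand-texts of every reference.
# Hit j0 is 0-based on the strand-text; for the minus text of a reference of
# length L, a k-length window at j0 corresponds to genomic start0 = L-j0-k.
.kmerIndex <- function(texts, k) {
  km <- character(0); ref <- integer(0); j0 <- integer(0); st <- integer(0)
  for (i in seq_along(texts$plus)) {
    L <- texts$len[i]
    if (L < k) next
    n <- L - k + 1L
    km <- c(km, substring(texts$plus[i], 1:n, k:L),
                substring(texts$minus[i], 1:n, k:L))
    ref <- c(ref, rep(i, 2L * n))
    j0 <- c(j0, 0:(n - 1L), 0:(n - 1L))
    st <- c(st, rep(c(1L, 2L), each = n))
  }
  grp <- split(seq_along(km), km)
  list(grp = grp, ref = ref, j0 = j0, st = st)
}

.mismatchCount <- function(a, b) {
  # a, b equal-length character scalars
  sum(charToRaw(a) != charToRaw(b))
}

# map (refIdx, strandText, j0, k) hit triplets to alignment coordinates
.hitsToCoords <- function(texts, ref, st, j0, k) {
  L <- texts$len[ref]
  data.frame(
    refIdx = ref,
    start0 = ifelse(st == 1L, j0, L - j0 - k),
    strand = ifelse(st == 1L, "+", "-"),
    stringsAsFactors = FALSE)
}

#' Align short reads to references at 0 or 1 mismatch
#'
#' Returns every placement at the minimal achievable mismatch count up to
#' `maxMismatch`, over both strands of every reference (best-stratum
#' semantics: if a read has any perfect placement, 1-mismatch placements
#' are suppressed). Each placement is weighted 1 / (number of placements of
#' that read) so that every aligned read contributes total weight 1.
#' Placements are ordered by (reference, start0, strand) within a read.
#'
#' Exact placements are found by hashed k-mer lookup; 1-mismatch placements
#' by the pigeonhole principle (one half of the read must match exactly),
#' followed by verification. Both paths are exhaustive for these read and
#' reference sizes, matching a brute-force scan over every offset and both
#' strands.
#'
#' @param reads a \linkS4class{ReadSet}, named DNAStringSet or named
#'   character vector; read length must be >= 15 nt.
#' @param references named [Biostrings::DNAStringSet] or character vector.
#' @param maxMismatch 0 or 1.
#' @return data.frame with columns read_id, reference, start0 (0-based),
#'   length, strand, mismatches, weight, seq. Unaligned reads are absent.
#' @examples
#' ref <- c(chr = "ACGTACGTAAGGCCTTACGATCGATCGGATCC")
#' alignReads(c(r1 = "ACGTAAGGCCTTACGATCGA"), ref)
#' @export
alignReads <- function(reads, references, maxMismatch = 0L) {
  if (!maxMismatch %in% c(0L, 1L)) stop("maxMismatch must be 0 or 1")
  seqs <- if (is(reads, "ReadSet")) as.character(reads@reads)
          else if (is.character(reads)) reads else as.character(reads)
  if (length(seqs) == 0L)
    return(data.frame(read_id = character(0), reference = character(0),
                      start0 = integer(0), length = integer(0),
                      strand = character(0), mismatches = integer(0),
                      weight = numeric(0), seq = character(0),
                      stringsAsFactors = FALSE))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(seqs))
  if (any(nchar(seqs) < 15L)) stop("reads must be at least 15 nt")
  texts <- .refTexts(references)
  refNames <- names(texts$plus)

  pieces <- list()
  for (k in sort(unique(nchar(seqs)))) {
    sel <- which(nchar(seqs) == k)
    idx <- .kmerIndex(texts, k)
    hit <- idx$grp[match(seqs[sel], names(idx$grp))]
    nh <- lengths(hit)
    # exact placements
    if (any(nh > 0L)) {
      rows <- unlist(hit[nh > 0L], use.names = FALSE)
      co <- .hitsToCoords(texts, idx$ref[rows], idx$st[rows], idx$j0[rows], k)
      co$readPos <- rep(sel[nh > 0L], nh[nh > 0L])
      co$mismatches <- 0L
      pieces[[length(pieces) + 1L]] <- co
    }
    # 1-mismatch stratum via pigeonhole halves, only for exact misses
    if (maxMismatch == 1L && any(nh == 0L)) {
      miss <- sel[nh == 0L]
      h1 <- k %/% 2L; h2 <- k - h1
      idxL <- .kmerIndex(texts, h1)
      idxR <- .kmerIndex(texts, h2)
      left <- substr(seqs[miss], 1L, h1)
      right <- substr(seqs[miss], h1 + 1L, k)
      hitL <- idxL$grp[match(left, names(idxL$grp))]
      hitR <- idxR$grp[match(right, names(idxR$grp))]
      for (m in seq_along(miss)) {
        cand <- NULL
        rl <- hitL[[m]]
        if (length(rl))
          cand <- data.frame(ref = idxL$ref[rl], st = idxL$st[rl],
                             j0 = idxL$j0[rl])
        rr <- hitR[[m]]
        if (length(rr))
          cand <- rbind(cand, data.frame(ref = idxR$ref[rr],
                                         st = idxR$st[rr],
                                         j0 = idxR$j0[rr] - h1))
        if (is.null(cand)) next
        cand <- cand[cand$j0 >= 0L & cand$j0 + k <= texts$len[cand$ref], ,
                     drop = FALSE]
        if (!nrow(cand)) next
        cand <- unique(cand)
        txt <- ifelse(cand$st == 1L, texts$plus[cand$ref],
                      texts$minus[cand$ref])
        win <- substring(txt, cand$j0 + 1L, cand$j0 + k)
        mm <- vapply(win, .mismatchCount, integer(1), b = seqs[miss[m]],
                     USE.NAMES = FALSE)
        keep <- which(mm <= 1L)
        if (!length(keep)) next
        co <- .hitsToCoords(texts, cand$ref[keep], cand$st[keep],
                            cand$j0[keep], k)
        co$readPos <- miss[m]
        co$mismatches <- mm[keep]
        pieces[[length(pieces) + 1L]] <- co
      }
    }
  }
  if (!length(pieces))
    return(data.frame(read_id = character(0), reference = character(0),
                      start0 = integer(0), length = integer(0),
                      strand = character(0), mismatches = integer(0),
                      weight = numeric(0), seq = character(0),
                      stringsAsFactors = FALSE))
  co <- do.call(rbind, pieces)
  # best stratum per read, then fractional weights and deterministic order
  best <- tapply(co$mismatches, co$readPos, min)
  co <- co[co$mismatches == best[as.character(co$readPos)], , drop = FALSE]
  nPlace <- table(co$readPos)
  co$weight <- 1 / as.integer(nPlace[as.character(co$readPos)])
  out <- data.frame(
    read_id = ids[co$readPos],
    reference = refNames[co$refIdx],
    start0 = as.integer(co$start0),
    length = nchar(seqs[co$readPos]),
    strand = co$strand,
    mismatches = as.integer(co$mismatches),
    weight = co$weight,
    seq = seqs[co$readPos],
    stringsAsFactors = FALSE)
  out <- out[order(co$readPos, out$reference, out$start0, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# --------------------------------------------------------------- summaries

#' Weighted read-length histogram
#'
#' Sums alignment weights per read length inside `window`. Because every
#' aligned read carries total weight 1 across its placements, the histogram
#' counts reads, not placements.
#'
#' @param aln alignment data.frame from [alignReads()].
#' @param window inclusive length window, within \[15, 30\].
#' @param librarySize total reads in the library (aligned or not); used by
#'   ppm normalization downstream.
#' @return list with `counts` (named numeric over the window lengths),
#'   `mapped` (total weight inside the window) and `librarySize`.
#' @export
sizeDistribution <- function(aln, window = c(17L, 24L), librarySize = NA) {
  if (window[1] < 15L || window[2] > 30L || window[1] > window[2])
    stop("window must lie within [15, 30]")
  lens <- window[1]:window[2]
  counts <- setNames(numeric(length(lens)), lens)
  keep <- aln$length >= window[1] & aln$length <= window[2]
  if (any(keep)) {
    s <- tapply(aln$weight[keep], aln$length[keep], sum)
    counts[names(s)] <- as.numeric(s)
  }
  list(counts = counts, mapped = sum(counts), librarySize = librarySize)
}

#' Parts-per-million normalization
#'
#' @param count weighted read count.
#' @param librarySize total reads in the library (> 0).
#' @return `count / librarySize * 1e6`.
#' @examples
#' ppm(13, 20000)  # 650
#' @export
ppm <- function(count, librarySize) {
  if (any(librarySize <= 0)) stop("librarySize must be > 0")
  count / librarySize * 1e6
}

#' Stranded 5'-end positional profile
#'
#' Accumulates alignment weights at the 5'-end position of every placement
#' on one reference: `start0` for (+)-strand placements and
#' `start0 + length - 1` for (-)-strand placements.
#'
#' @param aln alignment data.frame.
#' @param reference reference name to profile.
#' @param refLength its length in nt.
#' @param sizeFilter optional integer vector of read lengths to keep.
#' @return list with `reference`, `plus` and `minus` (numeric vectors of
#'   length `refLength`, index i = position i-1) and `sizeFilter`.
#' @export
fivePrimeProfile <- function(aln, reference, refLength, sizeFilter = NULL) {
  a <- aln[aln$reference == reference, , drop = FALSE]
  if (!is.null(sizeFilter)) a <- a[a$length %in% sizeFilter, , drop = FALSE]
  p5 <- ifelse(a$strand == "+", a$start0, a$start0 + a$length - 1L)
  plus <- .accumulate(p5[a$strand == "+"] + 1L, a$weight[a$strand == "+"],
                      refLength)
  minus <- .accumulate(p5[a$strand == "-"] + 1L, a$weight[a$strand == "-"],
                       refLength)
  list(reference = reference, plus = plus, minus = minus,
       sizeFilter = sizeFilter)
}

#' Count distinct read sequences at a reference/strand
#'
#' @param aln alignment data.frame.
#' @param reference reference name.
#' @param strand "+", "-" or NULL for both.
#' @return integer count of distinct aligned read sequences.
#' @export
countUniqueSequences <- function(aln, reference, strand = NULL) {
  a <- aln[aln$reference == reference, , drop = FALSE]
  if (!is.null(strand)) a <- a[a$strand == strand, , drop = FALSE]
  length(unique(a$seq))
}

#' Per-position stranded coverage from alignments
#'
#' Adds each placement's weight over its full interval, per strand.
#'
#' @param aln alignment data.frame.
#' @param refLengths named integer vector of reference lengths.
#' @return named list; per reference a list with numeric `plus` and
#'   `minus` vectors (index i = position i-1).
#' @export
strandedCoverage <- function(aln, refLengths) {
  out <- list()
  for (nm in names(refLengths)) {
    L <- refLengths[[nm]]
    out[[nm]] <- list(plus = numeric(L), minus = numeric(L))
    a <- aln[aln$reference == nm, , drop = FALSE]
    for (st in c("+", "-")) {
      b <- a[a$strand == st, , drop = FALSE]
      d <- numeric(L + 1L)
      if (nrow(b)) {
        add <- tapply(b$weight, b$start0 + 1L, sum)
        d[as.integer(names(add))] <- d[as.integer(names(add))] + add
        sub <- tapply(b$weight, pmin(b$start0 + b$length, L) + 1L, sum)
        d[as.integer(names(sub))] <- d[as.integer(names(sub))] - sub
      }
      v <- cumsum(d)[seq_len(L)]
      out[[nm]][[if (st == "+") "plus" else "minus"]] <- v
    }
  }
  out
}
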