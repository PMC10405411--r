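#' Default thresholds for antisense locus classification
#'
#' \describe{
#'   \item{minPpm}{minimum 21+22-nt antisense sRNA signal, ppm of the
#'     library (default 5): the "sufficiently expressed" floor.}
#'   \item{minSymmetry}{minimum strand symmetry `2*min(s,a)/(s+a)` for an
#'     annotated pair call (default 0.2).}
#'   \item{minAntisenseRna}{minimum mean stranded RNA-seq coverage on the
#'     antisense strand for a novel-antisense call (default 1 read/nt).}
#'   \item{maxGap}{maximum intergenic distance to a convergent partner for
#'     a readthrough call (default 300 nt).}
#'   \item{minGapCover}{minimum fraction of intergenic positions with
#'     antisense-strand RNA coverage for a readthrough call (default 0.5).}
#' }
#'
#' @return named list of thresholds.
#' @export
defaultThresholds <- function() {
  list(minPpm = 5, minSymmetry = 0.2, minAntisenseRna = 1,
       maxGap = 300L, minGapCover = 0.5)
}

#' Per-locus stranded sRNA and RNA-seq summaries
#'
#' For every annotated gene, tallies the weighted 21- and 22-nt sRNA
#' alignments whose 5' end lies inside the locus, split into sense and
#' antisense relative to the annotated gene strand and normalized to ppm
#' of the sRNA library; computes mean stranded RNA-seq coverage over the
#' locus per strand; and records locus context: whether an annotated gene
#' overlaps on the opposite strand, the distance to the nearest convergent
#' downstream gene, and the fraction of that intergenic gap covered by
#' antisense-strand RNA.
#'
#' @param aln sRNA alignment data.frame.
#' @param annotation gene `GRanges` (as in a \linkS4class{Minigenome}).
#' @param coverage stranded RNA-seq coverage from [strandedCoverage()].
#' @param librarySize total sRNA reads in the library.
#' @param sizes sRNA sizes counted (default 21 and 22 nt).
#' @return data.frame with one row per gene: locus, chrom, start0, end0,
#'   strand, gene_class (planted class, carried through for convenience),
#'   sense_srna_ppm, antisense_srna_ppm, sense_rna, antisense_rna,
#'   annotated_antisense_overlap, convergent_gap, gap_antisense_cover.
#' @export
locusStrandCounts <- function(aln, annotation, coverage, librarySize,
                              sizes = c(21L, 22L)) {
  g <- annotation
  if (length(g) == 0L) stop("locus absent from annotation")
  ids <- mcols(g)$gene_id
  chrom <- as.character(seqnames(g))
  gStrand <- as.character(strand(g))
  s0 <- start(g) - 1L; e0 <- end(g)
  a <- aln[aln$length %in% sizes, , drop = FALSE]
  p5 <- ifelse(a$strand == "+", a$start0, a$start0 + a$length - 1L)
  senseW <- antiW <- numeric(length(g))
  for (i in seq_along(g)) {
    sel <- a$reference == chrom[i] & p5 >= s0[i] & p5 < e0[i]
    if (any(sel)) {
      sameStrand <- a$strand[sel] == gStrand[i]
      senseW[i] <- sum(a$weight[sel][sameStrand])
      antiW[i] <- sum(a$weight[sel][!sameStrand])
    }
  }
  senseRna <- antiRna <- numeric(length(g))
  gapDist <- rep(NA_integer_, length(g))
  gapCover <- rep(NA_real_, length(g))
  for (i in seq_along(g)) {
    cv <- coverage[[chrom[i]]]
    if (!is.null(cv)) {
      idx <- (s0[i] + 1L):e0[i]
      plusMean <- mean(cv$plus[idx]); minusMean <- mean(cv$minus[idx])
      if (gStrand[i] == "+") {
        senseRna[i] <- plusMean; antiRna[i] <- minusMean
      } else {
        senseRna[i] <- minusMean; antiRna[i] <- plusMean
      }
    }
    # nearest convergent downstream gene (head-to-head orientation)
    if (gStrand[i] == "+") {
      cand <- which(chrom == chrom[i] & gStrand == "-" & s0 >= e0[i])
      if (length(cand)) {
        j <- cand[which.min(s0[cand])]
        gapDist[i] <- s0[j] - e0[i]
        gapIdx <- if (gapDist[i] > 0L) (e0[i] + 1L):s0[j] else integer(0)
        gapCover[i] <- if (length(gapIdx) && !is.null(cv))
          mean(cv$minus[gapIdx] > 0) else 1
      }
    } else {
      cand <- which(chrom == chrom[i] & gStrand == "+" & e0 <= s0[i])
      if (length(cand)) {
        j <- cand[which.max(e0[cand])]
        gapDist[i] <- s0[i] - e0[j]
        gapIdx <- if (gapDist[i] > 0L) (e0[j] + 1L):s0[i] else integer(0)
        gapCover[i] <- if (length(gapIdx) && !is.null(cv))
          mean(cv$plus[gapIdx] > 0) else 1
      }
    }
  }
  # annotated opposite-strand overlap with any other gene
  ovFlag <- logical(length(g))
  ov <- findOverlaps(g, g, ignore.strand = TRUE)
  qh <- queryHits(ov); sh <- subjectHits(ov)
  for (h in seq_along(qh)) {
    if (qh[h] != sh[h] && gStrand[qh[h]] != gStrand[sh[h]])
      ovFlag[qh[h]] <- TRUE
  }
  data.frame(
    locus = ids, chrom = chrom, start0 = s0, end0 = e0, strand = gStrand,
    gene_class = mcols(g)$class,
    sense_srna_ppm = ppm(senseW, librarySize),
    antisense_srna_ppm = ppm(antiW, librarySize),
    sense_rna = senseRna, antisense_rna = antiRna,
    annotated_antisense_overlap = ovFlag,
    convergent_gap = gapDist, gap_antisense_cover = gapCover,
    stringsAsFactors = FALSE)
}

#' Strand symmetry of an sRNA signal
#'
#' `2 * min(s, a) / (s + a)`: 1 for perfectly symmetric sense/antisense
#' production (the signature of dsRNA processing), 0 for single-stranded
#' signal.
#'
#' @param sense,antisense non-negative counts; not both zero.
#' @return numeric in \[0, 1\].
#' @examples
#' symmetryScore(100, 100)
#' symmetryScore(100, 0)
#' @export
symmetryScore <- function(sense, antisense) {
  if (any(sense < 0 | antisense < 0)) stop("counts must be non-negative")
  tot <- sense + antisense
  if (any(tot == 0)) stop("sense and antisense cannot both be zero")
  2 * pmin(sense, antisense) / tot
}

#' Classify one locus by its antisense signature
#'
#' Decision cascade over a [locusStrandCounts()] row:
#' \enumerate{
#'   \item antisense sRNA >= minPpm, symmetry >= minSymmetry and an
#'     annotated opposite-strand overlap: `annotated_antisense_pair`;
#'   \item else a convergent gene within maxGap whose intergenic gap is
#'     covered by antisense RNA and antisense sRNA >= minPpm:
#'     `readthrough_overlap`;
#'   \item else antisense RNA coverage >= minAntisenseRna and antisense
#'     sRNA >= minPpm: `novel_antisense`;
#'   \item else `none`.
#' }
#'
#' @param counts one-row data.frame from [locusStrandCounts()].
#' @param thresholds list as from [defaultThresholds()].
#' @return data.frame row: locus, class, symmetry, evidence.
#' @export
classifyLocus <- function(counts, thresholds = defaultThresholds()) {
  req <- c("minPpm", "minSymmetry", "minAntisenseRna", "maxGap",
           "minGapCover")
  if (!all(req %in% names(thresholds)) ||
      !all(vapply(thresholds[req], is.numeric, logical(1))))
    stop("malformed thresholds; need numeric ", paste(req, collapse = ", "))
  s <- counts$sense_srna_ppm; a <- counts$antisense_srna_ppm
  sym <- if (s + a > 0) symmetryScore(s, a) else NA_real_
  cls <- "none"; ev <- "no antisense sRNA signal"
  if (a >= thresholds$minPpm && !is.na(sym) &&
      sym >= thresholds$minSymmetry &&
      isTRUE(counts$annotated_antisense_overlap)) {
    cls <- "annotated_antisense_pair"
    ev <- sprintf("antisense %.1f ppm, symmetry %.2f, annotated overlap",
                  a, sym)
  } else if (a >= thresholds$minPpm && !is.na(counts$convergent_gap) &&
             counts$convergent_gap <= thresholds$maxGap &&
             !is.na(counts$gap_antisense_cover) &&
             counts$gap_antisense_cover >= thresholds$minGapCover) {
    cls <- "readthrough_overlap"
    ev <- sprintf(
      "antisense %.1f ppm, convergent gene at %d nt, gap cover %.2f",
      a, counts$convergent_gap, counts$gap_antisense_cover)
  } else if (a >= thresholds$minPpm &&
             counts$antisense_rna >= thresholds$minAntisenseRna) {
    cls <- "novel_antisense"
    ev <- sprintf("antisense %.1f ppm with %.2f reads/nt antisense RNA",
                  a, counts$antisense_rna)
  }
  data.frame(locus = counts$locus, class = cls, symmetry = sym,
             evidence = ev, stringsAsFactors = FALSE)
}

#' Classify every annotated locus
#'
#' @param aln sRNA alignment data.frame.
#' @param annotation gene `GRanges`.
#' @param coverage stranded RNA-seq coverage from [strandedCoverage()].
#' @param librarySize total sRNA reads.
#' @param thresholds list as from [defaultThresholds()].
#' @return data.frame with one row per locus: the [locusStrandCounts()]
#'   columns plus class, symmetry and evidence.
#' @export
callGenome <- function(aln, annotation, coverage, librarySize,
                       thresholds = defaultThresholds()) {
  counts <- locusStrandCounts(aln, annotation, coverage, librarySize)
  calls <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    classifyLocus(counts[i, , drop = FALSE], thresholds)))
  cbind(counts, calls[, c("class", "symmetry", "evidence")])
}

#' Write antisense calls as BED6
#'
#' Name field is `locus|class`; the score field carries the symmetry score
#' scaled to \[0, 1000\].
#'
#' @param calls data.frame from [callGenome()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeCallsBed <- function(calls, path) {
  score <- ifelse(is.na(calls$symmetry), 0,
                  as.integer(round(calls$symmetry * 1000)))
  bed <- data.frame(calls$chrom, calls$start0, calls$end0,
                    paste(calls$locus, calls$class, sep = "|"),
                    score, calls$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Expected call class for planted locus archetypes
#'
#' Maps the generator's planted gene classes to the call the classifier
#' should make: antisense_pair_member -> annotated_antisense_pair,
#' readthrough_member -> readthrough_overlap, hidden_antisense ->
#' novel_antisense, and plain/repeat -> none (repeats produce abundant
#' sRNA but no antisense transcription).
#'
#' @param annotation gene `GRanges` with the planted `class` column.
#' @return named character vector of expected classes per gene id.
#' @export
plantedTruth <- function(annotation) {
  map <- c(plain = "none", antisense_pair_member = "annotated_antisense_pair",
           readthrough_member = "readthrough_overlap",
           hidden_antisense = "novel_antisense", "repeat" = "none")
  setNames(unname(map[mcols(annotation)$class]),
           mcols(annotation)$gene_id)
}
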