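#' Count RNA-seq reads per gene
#'
#' A read is assigned to the gene whose interval contains its 5' end on the
#' matching strand. Reads whose placements resolve to no gene are dropped;
#' reads resolving to more than one distinct gene (multireads across
#' repeat copies, for instance) are ambiguous and discarded.
#'
#' @param aln stranded RNA-seq alignment data.frame from [alignReads()].
#' @param annotation gene `GRanges`.
#' @return named integer vector of counts per gene id.
#' @export
countGenes <- function(aln, annotation) {
  g <- annotation
  ids <- mcols(g)$gene_id
  counts <- setNames(integer(length(g)), ids)
  if (!nrow(aln)) return(counts)
  chrom <- as.character(seqnames(g))
  gStrand <- as.character(strand(g))
  s0 <- start(g) - 1L; e0 <- end(g)
  p5 <- ifelse(aln$strand == "+", aln$start0, aln$start0 + aln$length - 1L)
  # per placement, which gene (if any) contains the 5' end on its strand
  hit <- rep(NA_integer_, nrow(aln))
  for (i in seq_along(g)) {
    sel <- aln$reference == chrom[i] & aln$strand == gStrand[i] &
           p5 >= s0[i] & p5 < e0[i]
    hit[sel] <- i  # same-strand genes never overlap, so no clobbering
  }
  byRead <- split(hit, aln$read_id)
  resolved <- vapply(byRead, function(h) {
    u <- unique(h[!is.na(h)])
    if (length(u) == 1L) u else NA_integer_
  }, integer(1))
  resolved <- resolved[!is.na(resolved)]
  tb <- table(resolved)
  counts[as.integer(names(tb))] <- as.integer(tb)
  counts
}

#' Assemble a count matrix from per-sample counts
#'
#' @param countList named list of count vectors (one per sample, same gene
#'   order).
#' @param conditions character vector of condition labels per sample.
#' @return list with integer `counts` matrix (genes x samples) and
#'   `conditions`.
#' @export
countMatrix <- function(countList, conditions) {
  stopifnot(length(countList) == length(conditions))
  m <- do.call(cbind, countList)
  if (is.null(colnames(m))) colnames(m) <- names(countList)
  if (any(m < 0)) stop("counts must be non-negative")
  list(counts = m, conditions = conditions)
}

#' Median-of-ratios normalization
#'
#' Per-sample size factor = median over reference genes (those with
#' non-zero counts in every sample) of count / geometric mean; baseMean =
#' mean of size-factor-normalized counts per gene.
#'
#' @param counts genes x samples integer matrix.
#' @return list with `sizeFactors`, `normalized` matrix and `baseMean`.
#' @export
normalizeMedianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) {
    sf <- setNames(1, colnames(counts))
    norm <- counts
    return(list(sizeFactors = sf, normalized = norm,
                baseMean = rowMeans(norm)))
  }
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) stop("no gene with non-zero counts in all samples")
  logGeo <- rowMeans(log(counts[ok, , drop = FALSE]))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col)
    median(exp(log(col) - logGeo)))
  # standardize to median 1: rescaling one sample's counts then moves only
  # that sample's factor, leaving every normalized count unchanged
  sf <- sf / median(sf)
  norm <- sweep(counts, 2, sf, "/")
  list(sizeFactors = sf, normalized = norm, baseMean = rowMeans(norm))
}

#' Negative-binomial Wald test for two-condition differential expression
#'
#' Per gene: size factors by median-of-ratios (unless supplied), a pooled
#' method-of-moments NB dispersion floored at 1e-8, a log2 fold change of
#' normalized condition means with pseudo-count 0.5, a Wald statistic from
#' the model variance `mu/sf + alpha*mu^2` of each replicate mean, a
#' two-sided normal p-value, and Benjamini-Hochberg adjustment across
#' genes. No dispersion shrinkage or outlier handling is performed.
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @param conditions length-ncol character vector with exactly two levels,
#'   >= 2 replicates each.
#' @param sizeFactors optional fixed size factors.
#' @param dispersion optional fixed per-gene dispersion(s), recycled.
#' @return data.frame: gene, baseMean, log2FC (second level over first),
#'   p, padj, significant (see [filterSignificant()]).
#' @export
nbWaldTest <- function(counts, conditions, sizeFactors = NULL,
                       dispersion = NULL) {
  counts <- as.matrix(counts)
  lev <- unique(conditions)
  if (length(lev) != 2L) stop("exactly two conditions required")
  iA <- which(conditions == lev[1]); iB <- which(conditions == lev[2])
  if (length(iA) < 2L || length(iB) < 2L)
    stop("need at least two replicates per condition")
  if (any(colSums(counts[, c(iA, iB), drop = FALSE]) == 0))
    stop("a condition contains an all-zero library")
  if (is.null(sizeFactors)) {
    sizeFactors <- normalizeMedianOfRatios(counts)$sizeFactors
  }
  norm <- sweep(counts, 2, sizeFactors, "/")
  baseMean <- rowMeans(norm)
  muA <- rowMeans(norm[, iA, drop = FALSE])
  muB <- rowMeans(norm[, iB, drop = FALSE])
  nA <- length(iA); nB <- length(iB)
  if (is.null(dispersion)) {
    varA <- apply(norm[, iA, drop = FALSE], 1, var)
    varB <- apply(norm[, iB, drop = FALSE], 1, var)
    s2 <- (varA * (nA - 1) + varB * (nB - 1)) / (nA + nB - 2)
    mu <- (muA * nA + muB * nB) / (nA + nB)
    xim <- mean(1 / sizeFactors)
    alpha <- (s2 - xim * mu) / mu^2
    alpha[!is.finite(alpha)] <- 0
    # the pooled variance has few degrees of freedom at typical replicate
    # numbers; flooring each gene at the experiment-wide median dispersion
    # keeps chance variance under-estimates from inflating the Wald
    # statistic, without shrinking genuinely high dispersions
    common <- median(alpha[alpha > 0])
    if (is.finite(common)) alpha <- pmax(alpha, common)
  } else {
    alpha <- rep_len(dispersion, nrow(counts))
  }
  alpha <- pmax(alpha, 1e-8)
  varMeanA <- (muA * sum(1 / sizeFactors[iA]) / nA^2) + alpha * muA^2 / nA
  varMeanB <- (muB * sum(1 / sizeFactors[iB]) / nB^2) + alpha * muB^2 / nB
  l2fc <- log2((muB + 0.5) / (muA + 0.5))
  seLog <- sqrt(varMeanA / (muA + 0.5)^2 + varMeanB / (muB + 0.5)^2)
  z <- ifelse(seLog > 0, log((muB + 0.5) / (muA + 0.5)) / seLog, 0)
  p <- 2 * pnorm(-abs(z))
  p[muA + muB == 0] <- 1
  padj <- p.adjust(p, method = "BH")
  res <- data.frame(
    gene = if (!is.null(rownames(counts))) rownames(counts)
           else sprintf("gene%05d", seq_len(nrow(counts))),
    baseMean = baseMean, log2FC = l2fc, p = p, padj = padj,
    stringsAsFactors = FALSE)
  res$significant <- res$padj < 0.05 & res$baseMean > 50 &
    abs(res$log2FC) > 0.585
  res
}

#' Filter differential expression results for significance
#'
#' Keeps genes with BH-adjusted p < 0.05, mean normalized count > 50 and
#' |log2 fold change| > 0.585 (fold change > 1.5).
#'
#' @param results data.frame from [nbWaldTest()].
#' @return the significant subset.
#' @export
filterSignificant <- function(results) {
  results[results$padj < 0.05 & results$baseMean > 50 &
            abs(results$log2FC) > 0.585, , drop = FALSE]
}

#' Delta-delta-Ct relative expression
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) - (Ct_target,control -
#' Ct_ref,control)`; relative expression is `2^(-ddCt)`. A ddCt of 1
#' corresponds to a twofold knockdown (relative expression 0.5).
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl finite
#'   cycle-threshold values.
#' @return list with `ddct` and `relative_expression`.
#' @examples
#' computeDdct(21, 15, 20, 15)  # relative expression 0.5
#' @export
computeDdct <- function(ctTargetTreated, ctRefTreated, ctTargetControl,
                        ctRefControl) {
  vals <- c(ctTargetTreated, ctRefTreated, ctTargetControl, ctRefControl)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ctTargetTreated - ctRefTreated) -
          (ctTargetControl - ctRefControl)
  list(ddct = ddct, relative_expression = 2^(-ddct))
}
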