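#' Fraction of the library derived from the hairpin stem
#'
#' A read originates from the double-stranded portion iff its full aligned
#' interval lies inside one of the two stem intervals (not merely its 5'
#' end). Because the two arms are perfect inverted repeats, every stem read
#' has one placement per arm with weight 1/2 each, so summed weights count
#' reads once. Both normalizations of interest are returned: against the
#' total library and against the total aligned weight.
#'
#' @param aln alignment data.frame from [alignReads()].
#' @param hairpin a \linkS4class{HairpinConstruct}.
#' @param librarySize total reads in the library.
#' @param reference name of the hairpin reference in `aln`.
#' @return named numeric: `total` (stem weight / librarySize) and `mapped`
#'   (stem weight / aligned weight).
#' @export
hairpinFraction <- function(aln, hairpin, librarySize,
                            reference = "hairpin") {
  if (librarySize <= 0) stop("librarySize must be > 0")
  a <- hairpin@armLength; l <- hairpin@loopLength
  h <- aln[aln$reference == reference, , drop = FALSE]
  s <- h$start0; e <- h$start0 + h$length
  inStem <- (s >= 0L & e <= a) | (s >= a + l & e <= 2L * a + l)
  stemW <- sum(h$weight[inStem])
  mappedW <- sum(aln$weight)
  c(total = stemW / librarySize,
    mapped = if (mappedW > 0) stemW / mappedW else 0)
}

#' Fisher's exact test for an sRNA production drop at a position
#'
#' Tests whether 5'-end counts differ between the windows `[b-w, b)` and
#' `[b, b+w)` of a positional profile (plus and minus strands pooled),
#' against the equal-production expectation represented by a reference row
#' of `w` positions per window: the 2x2 table is
#' \{(left counts, right counts), (w, w)\}, counts rounded to integers,
#' evaluated with a two-sided Fisher exact test. The small expectation row
#' makes the test conservative at high depth, so only strong positional
#' drops -- such as the stem/loop border -- reach significance.
#'
#' @param profile positional profile from [fivePrimeProfile()].
#' @param b candidate boundary, 0-based position.
#' @param w window width in nt (>= 5).
#' @return list with `boundary`, `p_value`, `window`, `direction`
#'   ("into_loop_from_left" when production drops left-to-right, else
#'   "into_loop_from_right"), and the rounded window counts `left`,
#'   `right`.
#' @export
loopBoundaryTest <- function(profile, b, w = 20L) {
  x <- profile$plus + profile$minus
  L <- length(x)
  if (sum(x) == 0) stop("empty positional profile")
  if (w < 5L) stop("window must be at least 5 nt")
  if (b - w < 0L || b + w > L) stop("windows out of range")
  left <- round(sum(x[(b - w + 1L):b]))
  right <- round(sum(x[(b + 1L):(b + w)]))
  p <- fisher.test(matrix(c(left, right, w, w), nrow = 2L,
                          byrow = TRUE))$p.value
  list(boundary = b, p_value = p, window = w,
       direction = if (left >= right) "into_loop_from_left"
                   else "into_loop_from_right",
       left = left, right = right)
}

#' Scan for the loop boundaries of a hairpin
#'
#' Evaluates [loopBoundaryTest()] at every position within `w` of each
#' annotated loop edge and reports, per edge, the position with the
#' smallest p-value together with a Bonferroni-corrected p-value over the
#' positions scanned.
#'
#' @param profile positional profile of the hairpin reference.
#' @param hairpin a \linkS4class{HairpinConstruct} (supplies the annotated
#'   loop edges).
#' @param w window width in nt.
#' @return data.frame, one row per edge: edge ("left"/"right"), boundary,
#'   p_value, p_adj, direction, n_scanned.
#' @export
scanBoundary <- function(profile, hairpin, w = 20L) {
  if (hairpin@loopLength < 1L) stop("loop length must be >= 1")
  a <- hairpin@armLength; l <- hairpin@loopLength
  L <- 2L * a + l
  edges <- c(left = a, right = a + l)
  out <- lapply(names(edges), function(nm) {
    e <- edges[[nm]]
    cand <- max(w, e - w):min(L - w, e + w)
    calls <- lapply(cand, function(b) loopBoundaryTest(profile, b, w))
    pv <- vapply(calls, `[[`, numeric(1), "p_value")
    best <- which.min(pv)
    data.frame(edge = nm, boundary = cand[best], p_value = pv[best],
               p_adj = min(1, pv[best] * length(cand)),
               direction = calls[[best]]$direction,
               n_scanned = length(cand), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-size positional profiles
#'
#' One 5'-end profile per product size; their totals sum to the aligned
#' weight of reads in those sizes.
#'
#' @param aln alignment data.frame.
#' @param reference reference name.
#' @param refLength reference length.
#' @param sizes integer vector of sizes, default 20:22.
#' @return named list of profiles (see [fivePrimeProfile()]).
#' @export
perSizeProfiles <- function(aln, reference, refLength, sizes = 20:22) {
  setNames(lapply(sizes, function(k)
    fivePrimeProfile(aln, reference, refLength, sizeFilter = k)),
    as.character(sizes))
}
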