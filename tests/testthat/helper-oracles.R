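# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the aligner oracle scans every offset of both
# strands, the BH oracle is the textbook step-up, and the Fisher oracle
# sums hypergeometric point masses directly.

# exhaustive all-offsets/both-strands scan; returns best-stratum placements
# ordered (reference, start0, strand) like alignReads()
bruteForceAlign <- function(seq, refChar, maxMismatch) {
  rcChar <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(refChar)))
  k <- nchar(seq)
  ri <- utf8ToInt(seq)
  out <- NULL
  for (nm in names(refChar)) {
    for (st in c("+", "-")) {
      txt <- if (st == "+") refChar[[nm]] else rcChar[[nm]]
      ti <- utf8ToInt(txt)
      L <- length(ti)
      if (L < k) next
      mm <- integer(L - k + 1L)
      for (j in 1:k) mm <- mm + (ti[j:(L - k + j)] != ri[j])
      hit <- which(mm <= maxMismatch) - 1L
      if (length(hit)) {
        s0 <- if (st == "+") hit else L - hit - k
        out <- rbind(out, data.frame(reference = nm, start0 = s0,
                                     strand = st,
                                     mismatches = mm[hit + 1L],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) return(NULL)
  out <- out[out$mismatches == min(out$mismatches), , drop = FALSE]
  out <- out[order(out$reference, out$start0, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# textbook Benjamini-Hochberg step-up
manualBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher exact p for the 2x2 table {(a, b), (c, d)} by direct
# hypergeometric enumeration
fisherOracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; kk <- a + b
  x <- max(0, kk - n):min(kk, m)
  pr <- dhyper(x, m, n, kk)
  pObs <- dhyper(a, m, n, kk)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# random read generator over a reference: exact / one-substitution /
# unrelated, on either orientation
randomReadsFor <- function(refChar, n, k = 21L, seed = 1L) {
  set.seed(seed)
  L <- nchar(refChar[[1]])
  mk <- function(i) {
    kind <- i %% 3L
    if (kind == 0L) {
      return(paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""))
    }
    s <- sample.int(L - k, 1L)
    r <- substr(refChar[[1]], s, s + k - 1L)
    if (kind == 1L) {
      p <- sample.int(k, 1L)
      ch <- strsplit(r, "")[[1]]
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      r <- paste(ch, collapse = "")
    }
    if (runif(1) < 0.5)
      r <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(r)))
    r
  }
  out <- vapply(seq_len(n), mk, character(1))
  names(out) <- sprintf("r%05d", seq_len(n))
  out
}

# shared small fixtures
hp275 <- buildHairpin(275, 79, seed = 1)
hpRefs <- c(hairpin = as.character(transcriptSequence(hp275)))
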