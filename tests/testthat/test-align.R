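# Trimming, alignment semantics (oracle equivalence, weights, strands),
# size histograms, ppm and positional profiles.

test_that("adapter trimming keeps the insert and enforces the window", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- strrep("ACGTA", 5)  # 25 nt -> trimmed inserts built below
  r21 <- paste0(substr(insert, 1, 21), adapter)
  out <- trimAdapter(c(a = r21), adapter)
  expect_identical(unname(out), substr(insert, 1, 21))

  # too short after trimming is discarded
  r10 <- paste0(substr(insert, 1, 10), adapter)
  expect_identical(length(trimAdapter(c(a = r10), adapter)), 0L)

  # untrimmable read inside the window is kept unchanged
  r22 <- substr(paste0(insert, insert), 1, 22)
  expect_identical(unname(trimAdapter(c(a = r22), adapter)), r22)

  # untrimmable read longer than the window is discarded
  r30 <- substr(paste0(insert, insert), 1, 30)
  expect_identical(length(trimAdapter(c(a = r30), adapter)), 0L)
})

test_that("single-placement reads align as expected on both strands", {
  set.seed(11)
  ref <- c(chrQ = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                        collapse = ""))
  sub <- substr(ref[[1]], 101, 121)
  aln <- alignReads(c(fwd = sub), ref, 0)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$start0, 100L)
  expect_identical(aln$strand, "+")
  expect_identical(aln$mismatches, 0L)
  expect_identical(aln$weight, 1)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  aln2 <- alignReads(c(rev = rc), ref, 0)
  expect_identical(nrow(aln2), 1L)
  expect_identical(aln2$start0, 100L)
  expect_identical(aln2$strand, "-")

  expect_error(alignReads(c(a = sub), character(0), 0), "empty reference")
})

test_that("aligner matches the brute-force scan at 0 and 1 mismatch", {
  set.seed(21)
  ref <- c(chrT = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                        collapse = ""))
  rds <- randomReadsFor(ref, 300, k = 21L, seed = 33)
  for (mm in 0:1) {
    aln <- alignReads(rds, ref, mm)
    for (i in seq_along(rds)) {
      b <- bruteForceAlign(rds[[i]], ref, mm)
      a <- aln[aln$read_id == names(rds)[i],
               c("reference", "start0", "strand", "mismatches")]
      rownames(a) <- NULL
      if (is.null(b)) {
        expect_identical(nrow(a), 0L)
      } else {
        expect_equal(a, b, ignore_attr = TRUE)
      }
    }
  }
})

test_that("alignment weights sum to one per aligned read", {
  # a 2-copy repeat forces 2 placements at weight 1/2
  set.seed(5)
  unit <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  pad <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  ref <- c(chrR = paste0(pad, unit, pad, unit, pad))
  rd <- c(x = substr(unit, 10, 30))
  aln <- alignReads(rd, ref, 0)
  expect_identical(nrow(aln), 2L)
  expect_equal(sum(aln$weight), 1)
  expect_equal(aln$weight, c(0.5, 0.5))

  # weight conservation over a seeded library
  sim <- simulateDicerProducts(hp275, DicerModel(backgroundFraction = 0),
                               500, seed = 3)
  aln2 <- alignReads(sim$reads, hpRefs, 0)
  perRead <- tapply(aln2$weight, aln2$read_id, sum)
  expect_true(all(abs(perRead - 1) < 1e-9))
})

test_that("reverse-complementing all reads swaps strand totals exactly", {
  set.seed(31)
  ref <- c(chrS = paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                        collapse = ""))
  rds <- randomReadsFor(ref, 120, k = 20L, seed = 8)
  aln <- alignReads(rds, ref, 1)
  rcReads <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(rds)))
  names(rcReads) <- names(rds)
  alnRC <- alignReads(rcReads, ref, 1)
  plus <- sum(aln$weight[aln$strand == "+"])
  minus <- sum(aln$weight[aln$strand == "-"])
  expect_equal(sum(alnRC$weight[alnRC$strand == "-"]), plus)
  expect_equal(sum(alnRC$weight[alnRC$strand == "+"]), minus)
})

test_that("size histograms conserve aligned weight", {
  aln <- data.frame(read_id = c("a", "b", "c"), reference = "r",
                    start0 = 0L, length = c(21L, 21L, 22L), strand = "+",
                    mismatches = 0L, weight = 1, seq = "N")
  h <- sizeDistribution(aln, c(17, 24), librarySize = 10)
  expect_equal(unname(h$counts[c("21", "22")]), c(2, 1))
  expect_equal(h$mapped, 3)

  h0 <- sizeDistribution(aln[0, ], c(17, 24), 10)
  expect_true(all(h0$counts == 0))

  # generator ground truth: mode at 21 for weights .1/.6/.3
  sim <- simulateDicerProducts(hp275, DicerModel(backgroundFraction = 0),
                               10000, seed = 13)
  alnS <- alignReads(sim$reads, hpRefs, 0)
  hS <- sizeDistribution(alnS, c(17, 24), 10000)
  expect_identical(names(which.max(hS$counts)), "21")
  expect_equal(hS$mapped, sum(alnS$weight), tolerance = 1e-6)
  expect_error(sizeDistribution(aln, c(10, 24)), "window")
})

test_that("ppm is the paper's per-million unit and is linear", {
  expect_identical(ppm(650, 1e6), 650)
  expect_identical(ppm(0, 5), 0)
  expect_identical(ppm(13, 20000), 650)
  expect_error(ppm(1, 0), "librarySize")
  a <- runif(20) * 100; b <- runif(20) * 100
  expect_true(all(abs(ppm(a + b, 3e6) - (ppm(a, 3e6) + ppm(b, 3e6)))
                  < 1e-9))
})

test_that("5'-end profiles follow the strand convention", {
  aln <- data.frame(read_id = c("a", "b"), reference = "r",
                    start0 = c(5L, 5L), length = 21L,
                    strand = c("+", "-"), mismatches = 0L, weight = 1,
                    seq = "N")
  pr <- fivePrimeProfile(aln, "r", 60)
  expect_equal(pr$plus[6], 1)   # + strand: 5' end at start0 = 5
  expect_equal(pr$minus[26], 1) # - strand: 5' end at start0+len-1 = 25
  expect_equal(sum(pr$plus) + sum(pr$minus), 2)
})

test_that("unique sequence counting is per reference and strand", {
  aln <- data.frame(read_id = c("a", "b", "c"), reference = "r",
                    start0 = 0L, length = 21L, strand = "+",
                    mismatches = 0L, weight = 1,
                    seq = c("AAA", "AAA", "CCC"))
  expect_identical(countUniqueSequences(aln, "r", "+"), 2L)
  expect_identical(countUniqueSequences(aln, "r", "-"), 0L)
  expect_identical(countUniqueSequences(aln[0, ], "r"), 0L)
})

test_that("stranded coverage accumulates weights over full intervals", {
  aln <- data.frame(read_id = c("a", "b"), reference = "r",
                    start0 = c(2L, 4L), length = 4L,
                    strand = c("+", "-"), mismatches = 0L,
                    weight = c(1, 0.5), seq = "N")
  cov <- strandedCoverage(aln, c(r = 10L))
  expect_equal(cov$r$plus, c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(cov$r$minus, c(0, 0, 0, 0, 0.5, 0.5, 0.5, 0.5, 0, 0))
})
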