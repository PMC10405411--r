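# Gene counting, median-of-ratios normalization, the NB Wald test and its
# calibration, significance filtering, delta-delta-Ct.

test_that("gene counting assigns by 5'-end containment on matching strand", {
  g <- c(granges0("chr1", 100, 200, "+"), granges0("chr1", 300, 400, "-"))
  S4Vectors::mcols(g)$gene_id <- c("G1", "G2")
  aln <- data.frame(
    read_id = c("a", "b", "c", "d"),
    reference = "chr1",
    start0 = c(150L, 150L, 350L, 500L),
    length = 50L,
    strand = c("+", "-", "-", "+"),
    mismatches = 0L, weight = 1, seq = "N")
  cnt <- countGenes(aln, g)
  expect_identical(unname(cnt["G1"]), 1L)  # read a
  expect_identical(unname(cnt["G2"]), 1L)  # read c (5' end = 399 in G2)
  # read b is antisense to G1 with no antisense gene: uncounted
  expect_identical(sum(cnt), 2L)

  # a multiread across two genes is ambiguous and discarded
  aln2 <- data.frame(read_id = "m", reference = "chr1",
                     start0 = c(150L, 350L), length = 50L,
                     strand = c("+", "-"), mismatches = 0L,
                     weight = 0.5, seq = "N")
  expect_identical(sum(countGenes(aln2, g)), 0L)
})

test_that("counted expression ratios match the generator", {
  mg <- buildMinigenome(defaultMinigenomeSpec(), seed = 1)
  refs <- as.character(genomeSequences(mg))
  rs <- simulateRnaseq(mg, 30000, seed = 9, profile = c(PLN1 = 3, PLN3 = 1))
  cnt <- countGenes(alignReads(rs, refs, 0), genes(mg))
  n1 <- cnt[["PLN1"]]; n3 <- cnt[["PLN3"]]
  p <- n1 / (n1 + n3)
  se <- sqrt(0.75 * 0.25 / (n1 + n3))
  expect_lt(abs(p - 0.75), 3 * se)
})

test_that("median-of-ratios recovers depth scaling exactly and noisily", {
  set.seed(4)
  base <- rpois(200, lambda = 100)
  m <- cbind(s1 = base, s2 = 2L * base)
  nr <- normalizeMedianOfRatios(m)
  expect_equal(unname(nr$sizeFactors["s2"] / nr$sizeFactors["s1"]), 2)
  expect_equal(nr$normalized[, 1], nr$normalized[, 2],
               ignore_attr = TRUE)

  # single sample: factor 1
  one <- normalizeMedianOfRatios(m[, 1, drop = FALSE])
  expect_equal(unname(one$sizeFactors), 1)

  # Poisson counts at known depth ratios recovered within 5%
  set.seed(8)
  mu <- exp(runif(500, log(50), log(500)))
  depth <- c(1, 1.6, 0.7, 2.4)
  pm <- vapply(depth, function(d) rpois(500, mu * d), numeric(500))
  sf <- normalizeMedianOfRatios(pm)$sizeFactors
  rel <- (sf / sf[1]) / depth
  expect_true(all(abs(rel - 1) < 0.05))

  expect_error(normalizeMedianOfRatios(matrix(c(0, 1, 1, 0), 2)),
               "non-zero")
})

test_that("identical conditions give null results, BH matches step-up", {
  m <- matrix(rep(c(10, 200, 3000), 6), nrow = 3)
  rownames(m) <- c("g1", "g2", "g3")
  res <- nbWaldTest(m, rep(c("A", "B"), each = 3))
  expect_true(all(res$log2FC == 0))
  expect_true(all(res$p > 0.99))

  set.seed(12)
  cnt <- matrix(rnbinom(20 * 6, mu = 150, size = 10), nrow = 20)
  res2 <- nbWaldTest(cnt, rep(c("A", "B"), each = 3))
  expect_equal(res2$padj, manualBH(res2$p), tolerance = 1e-12)

  expect_error(nbWaldTest(cnt, rep("A", 6)), "two conditions")
  expect_error(nbWaldTest(cnt[, c(1, 4), drop = FALSE], c("A", "B")),
               "replicates")
  zero <- cnt; zero[, 4:6] <- 0L
  expect_error(nbWaldTest(zero, rep(c("A", "B"), each = 3)), "all-zero")
})

test_that("the Poisson limit agrees with the conditional binomial oracle", {
  a <- rep(c(250, 500, 1000, 2000), each = 13)[1:50]
  f <- rep(c(1, 1.03, 1.05, 1.1, 1.2, 1.4), times = 10)[1:50]
  b <- round(a * f)
  cnt <- cbind(a, a, a, b, b, b)
  res <- nbWaldTest(cnt, rep(c("A", "B"), each = 3),
                    sizeFactors = rep(1, 6))
  oracle <- vapply(seq_len(50), function(i)
    stats::binom.test(3 * b[i], 3 * (a[i] + b[i]), 0.5)$p.value, numeric(1))
  expect_lte(max(abs(res$p - oracle)), 0.02)
})

test_that("the test is calibrated under the NB null", {
  set.seed(42)
  n <- 2000
  mu <- exp(runif(n, log(20), log(2000)))
  cnt <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 1 / 0.1), nrow = n)
  res <- nbWaldTest(cnt, rep(c("A", "B"), each = 3))
  expect_lte(mean(res$padj < 0.05), 0.01)
})

test_that("true fourfold changes are recovered as log2FC 2 +- 0.2", {
  set.seed(7)
  cntA <- matrix(rnbinom(300, mu = 1000, size = 1 / 0.005), nrow = 100)
  cntB <- matrix(rnbinom(300, mu = 4000, size = 1 / 0.005), nrow = 100)
  res <- nbWaldTest(cbind(cntA, cntB), rep(c("A", "B"), each = 3),
                    sizeFactors = rep(1, 6))
  expect_gte(mean(abs(res$log2FC - 2) <= 0.2), 0.95)
})

test_that("scaling one sample changes only its size factor", {
  set.seed(3)
  cnt <- matrix(rnbinom(100 * 6, mu = 300, size = 10), nrow = 100)
  nr1 <- normalizeMedianOfRatios(cnt)
  res1 <- nbWaldTest(cnt, rep(c("A", "B"), each = 3))
  cnt2 <- cnt; cnt2[, 1] <- cnt2[, 1] * 5L
  nr2 <- normalizeMedianOfRatios(cnt2)
  res2 <- nbWaldTest(cnt2, rep(c("A", "B"), each = 3))
  # normalized counts, baseMean and fold changes are exactly invariant
  expect_equal(nr1$normalized, nr2$normalized, tolerance = 1e-9)
  expect_equal(res1$baseMean, res2$baseMean, tolerance = 1e-9)
  expect_equal(res1$log2FC, res2$log2FC, tolerance = 1e-9)
  expect_equal(unname(nr2$sizeFactors[1] / nr1$sizeFactors[1]), 5,
               tolerance = 1e-9)
  # p-values move only through the rescaled sample's shot-noise weight,
  # which is small against the NB dispersion term at these counts
  expect_equal(res1$p, res2$p, tolerance = 2e-3)
})

test_that("the significance filter applies all three thresholds", {
  res <- data.frame(
    gene = c("keep", "lowMean", "smallFC", "weakP"),
    baseMean = c(60, 40, 500, 500),
    log2FC = c(0.60, 2.0, 0.30, 3.0),
    p = c(0.01, 0.01, 0.01, 0.055),
    padj = c(0.04, 0.04, 0.04, 0.06))
  res$significant <- NA
  kept <- filterSignificant(res)
  expect_identical(kept$gene, "keep")
})

test_that("delta-delta-Ct gives the twofold-knockdown arithmetic", {
  expect_equal(computeDdct(21, 15, 20, 15)$relative_expression, 0.5)
  expect_equal(computeDdct(20, 15, 20, 15)$relative_expression, 1)
  expect_equal(computeDdct(18, 15, 20, 15)$relative_expression, 4)
  expect_error(computeDdct(NA, 15, 20, 15), "finite")
})
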