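# Generator module: hairpin arithmetic, minigenome construction, Dicer
# duplex geometry, replicon mutation model, RNA-seq allocation, file IO.

test_that("hairpin construction obeys the stem/loop arithmetic", {
  hp <- buildHairpin(275, 79, seed = 1)
  expect_identical(length(transcriptSequence(hp)), 629L)
  expect_identical(BiocGenerics::start(stemIntervals(hp)), c(1L, 355L))
  expect_identical(BiocGenerics::end(stemIntervals(hp)), c(275L, 629L))
  expect_identical(BiocGenerics::start(loopInterval(hp)), 276L)
  expect_identical(BiocGenerics::end(loopInterval(hp)), 354L)

  # degenerate arm
  hp0 <- buildHairpin(0, 50, seed = 2)
  expect_identical(length(transcriptSequence(hp0)), 50L)
  expect_identical(length(stemIntervals(hp0)), 0L)

  # small arithmetic case: stem [0,10) u [14,24), loop [10,14)
  hp10 <- buildHairpin(10, 4, seed = 3)
  expect_identical(BiocGenerics::start(stemIntervals(hp10)), c(1L, 15L))
  expect_identical(BiocGenerics::end(stemIntervals(hp10)), c(10L, 24L))
  expect_identical(BiocGenerics::start(loopInterval(hp10)), 11L)
  expect_identical(BiocGenerics::end(loopInterval(hp10)), 14L)

  # second arm is the exact reverse complement of the first
  s <- as.character(transcriptSequence(hp))
  arm1 <- substr(s, 1, 275)
  arm2 <- substr(s, 355, 629)
  expect_identical(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm1))),
    arm2)

  expect_error(buildHairpin(-1, 10), "armLength")
  expect_error(buildHairpin(10, 0), "loopLength")
})

test_that("minigenome construction is deterministic and validates bounds", {
  spec <- defaultMinigenomeSpec()
  mg1 <- buildMinigenome(spec, seed = 1)
  mg2 <- buildMinigenome(spec, seed = 1)
  expect_identical(as.character(genomeSequences(mg1)),
                   as.character(genomeSequences(mg2)))

  # written artifacts are byte-identical across runs
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  writeReference(mg1, fa1); writeReference(mg2, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  g1 <- tempfile(fileext = ".gff3"); g2 <- tempfile(fileext = ".gff3")
  writeAnnotation(mg1, g1); writeAnnotation(mg2, g2)
  expect_identical(readLines(g1), readLines(g2))

  # antisense pair members overlap reciprocally on opposite strands by
  # at least half the shorter gene
  g <- genes(mg1)
  pair <- g[S4Vectors::mcols(g)$class == "antisense_pair_member"]
  ov <- GenomicRanges::findOverlaps(pair, pair, ignore.strand = TRUE)
  opp <- as.character(BiocGenerics::strand(pair))[S4Vectors::queryHits(ov)] !=
         as.character(BiocGenerics::strand(pair))[S4Vectors::subjectHits(ov)]
  expect_true(any(opp))
  q <- S4Vectors::queryHits(ov)[opp][1]; s <- S4Vectors::subjectHits(ov)[opp][1]
  ovWidth <- min(BiocGenerics::end(pair)[c(q, s)]) -
             max(BiocGenerics::start(pair)[c(q, s)]) + 1
  expect_gte(ovWidth, 0.5 * min(BiocGenerics::width(pair)[c(q, s)]))

  # convergent readthrough pair with gap <= 200 nt
  rt <- g[S4Vectors::mcols(g)$class == "readthrough_member"]
  expect_identical(length(rt), 2L)
  gap <- max(BiocGenerics::start(rt)) - min(BiocGenerics::end(rt)) - 1
  expect_lte(gap, 200)

  # out-of-bounds gene is rejected
  bad <- spec
  badGenes <- genes(spec)
  BiocGenerics::end(badGenes)[1] <- 999999L
  expect_error(MinigenomeSpec(chromosomeLengths(spec), badGenes),
               "chromosome bounds")

  # overlapping same-strand genes are rejected
  badGenes2 <- genes(spec)
  shifted <- badGenes2[1]
  S4Vectors::mcols(shifted)$gene_id <- "DUP1"
  expect_error(MinigenomeSpec(chromosomeLengths(spec),
                              c(badGenes2, shifted)),
               "same-strand")
})

test_that("Dicer duplexes have equal strands and exact 2-nt 3' overhangs", {
  m <- DicerModel(backgroundFraction = 0)
  sim <- simulateDicerProducts(hp275, m, 10000, seed = 7)
  d <- sim$duplexes
  expect_identical(nrow(d), 10000L)
  expect_true(all(d$duplexType == "stem_pairing"))
  # guide and passenger have equal lengths
  expect_true(all(d$guideEnd - d$guideStart == d$size))
  expect_true(all(d$passengerEnd - d$passengerStart == d$size))
  # map the passenger through the fold (i <-> len-1-i) into guide-arm
  # coordinates; both offsets must be exactly the 2-nt 3' overhang
  len <- 629L
  mappedStart <- len - d$passengerEnd
  mappedEnd <- len - d$passengerStart
  expect_true(all(d$guideStart - mappedStart == 2L))
  expect_true(all(d$guideEnd - mappedEnd == 2L))

  # empirical size fractions within 3 binomial SE of the weights
  w <- sizeWeights(m)
  for (k in names(w)) {
    obs <- mean(d$size == as.integer(k))
    se <- sqrt(w[[k]] * (1 - w[[k]]) / nrow(d))
    expect_lt(abs(obs - w[[k]]), 3 * se)
  }

  # n = 0 is an empty product list
  sim0 <- simulateDicerProducts(hp275, m, 0, seed = 1)
  expect_identical(nrow(sim0$duplexes), 0L)
  expect_identical(length(sim0$reads), 0L)

  # no double-stranded region and no background is an error
  tiny <- buildHairpin(5, 30, seed = 1)
  expect_error(simulateDicerProducts(tiny, m, 10, seed = 1),
               "double-stranded")
})

test_that("loop exclusion is exhaustive at loopLeak = 0", {
  m <- DicerModel(loopLeak = 0, backgroundFraction = 0)
  sim <- simulateDicerProducts(hp275, m, 5000, seed = 9)
  d <- sim$duplexes
  # brute-force interval overlap scan against the loop [275, 354)
  guideHit <- d$guideStart < 354 & d$guideEnd > 275
  passHit <- d$passengerStart < 354 & d$passengerEnd > 275
  expect_identical(sum(guideHit | passHit), 0L)
  expect_identical(sum(d$overlapsLoop), 0L)
  # and the generator agrees with its own flag when leak is on
  simL <- simulateDicerProducts(hp275, DicerModel(loopLeak = 1,
                                                  backgroundFraction = 0),
                                2000, seed = 9)
  dl <- simL$duplexes
  recheck <- (dl$guideStart < 354 & dl$guideEnd > 275) |
             (dl$passengerStart < 354 & dl$passengerEnd > 275)
  expect_identical(recheck, dl$overlapsLoop)
})

test_that("replicon reads reflect mutation rate and accessibility", {
  # rate 0: every read is an exact substring of the replicon or its rc
  rm0 <- RepliconModel(perSiteMutationRate = 0, accessibility = 1, seed = 3)
  rs0 <- simulateRepliconReads(rm0, DicerModel(backgroundFraction = 0),
                               nMolecules = 50, productsPerMolecule = 5,
                               seed = 6)
  refs <- c(replicon = as.character(rm0@sequence))
  aln0 <- alignReads(rs0, refs, 0)
  expect_identical(length(unique(aln0$read_id)), length(rs0))
  expect_true(all(aln0$mismatches == 0))

  # closed form: P(>=1 mutated site in a 21-nt read) = 1 - 0.97^21
  rm3 <- RepliconModel(perSiteMutationRate = 0.03, accessibility = 1,
                       seed = 3)
  only21 <- DicerModel(sizeWeights = c(`21` = 1), backgroundFraction = 0)
  rs3 <- simulateRepliconReads(rm3, only21, nMolecules = 5000,
                               productsPerMolecule = 1, seed = 5)
  pv <- provenance(rs3)
  pExp <- 1 - 0.97^21
  se <- sqrt(pExp * (1 - pExp) / nrow(pv))
  expect_lt(abs(mean(pv$n_mutations >= 1) - pExp), 3 * se)

  # accessibility 0: no replicon-derived reads at all
  rmShut <- RepliconModel(accessibility = 0, seed = 3)
  expect_identical(length(simulateRepliconReads(rmShut, only21, 1000,
                                                seed = 2)), 0L)
})

test_that("RNA-seq read allocation follows expression, strand and class", {
  mg <- buildMinigenome(defaultMinigenomeSpec(), seed = 1)
  # 3:1 expression ratio between two equal-width genes
  rs <- simulateRnaseq(mg, 40000, seed = 5, profile = c(PLN1 = 3, PLN3 = 1))
  pv <- provenance(rs)
  n1 <- sum(pv$gene == "PLN1"); n3 <- sum(pv$gene == "PLN3")
  p <- n1 / (n1 + n3)
  se <- sqrt(0.75 * 0.25 / (n1 + n3))
  expect_lt(abs(p - 0.75), 3 * se)

  # hidden antisense fraction recovered
  h <- pv[pv$gene == "HAV1", ]
  frac <- mean(h$strand == "-")  # HAV1 is a + strand gene
  se <- sqrt(0.2 * 0.8 / nrow(h))
  expect_lt(abs(frac - 0.2), 3 * se)

  # empty request and unknown gene
  expect_identical(length(simulateRnaseq(mg, 0, seed = 1)), 0L)
  expect_error(simulateRnaseq(mg, 10, seed = 1, profile = c(NOPE = 1)),
               "unknown gene")
})

test_that("every emitted read id appears in provenance with coordinates", {
  m <- DicerModel(backgroundFraction = 0.3)
  sim <- simulateDicerProducts(hp275, m, 2000, seed = 4)
  rs <- sim$reads
  expect_true(all(names(reads(rs)) %in% provenance(rs)$read_id))
  pv <- provenance(rs)
  expect_true(all(pv$end0 > pv$start0))
  # provenance sequence check for hairpin-derived reads
  hpv <- pv[pv$substrate == "hairpin", ]
  tr <- as.character(transcriptSequence(hp275))
  recon <- substring(tr, hpv$start0 + 1, hpv$end0)
  flip <- hpv$strand == "-"
  recon[flip] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(recon[flip])))
  expect_identical(unname(as.character(reads(rs))[match(hpv$read_id,
                                                        names(reads(rs)))]),
                   unname(recon))
})

test_that("FASTQ, FASTA and GFF3 round-trips are exact", {
  rs <- simulateDicerProducts(hp275, DicerModel(backgroundFraction = 0),
                              3, seed = 1)$reads
  fq <- tempfile(fileext = ".fastq")
  writeReads(rs, fq)
  expect_identical(length(readLines(fq)), 12L)  # 3 reads x 4 lines
  back <- readFastqReads(fq)
  expect_identical(as.character(back), as.character(reads(rs)))

  mg <- buildMinigenome(defaultMinigenomeSpec(), seed = 2)
  fa <- tempfile(fileext = ".fa")
  writeReference(mg, fa)
  expect_identical(as.character(readReference(fa)),
                   as.character(genomeSequences(mg)))

  gff <- tempfile(fileext = ".gff3")
  writeAnnotation(mg, gff)
  ann <- readAnnotation(gff)
  g <- genes(mg)
  expect_identical(BiocGenerics::start(ann), BiocGenerics::start(g))
  expect_identical(BiocGenerics::end(ann), BiocGenerics::end(g))
  expect_identical(S4Vectors::mcols(ann)$gene_id,
                   S4Vectors::mcols(g)$gene_id)

  # GFF3 is 1-based inclusive: internal [10, 20) must print 11..20
  gr <- granges0("chrZ", 10, 20, "+")
  S4Vectors::mcols(gr)$gene_id <- "Z1"
  one <- tempfile(fileext = ".gff3")
  writeAnnotation(gr, one)
  line <- grep("^chrZ", readLines(one), value = TRUE)[1]
  f <- strsplit(line, "\t")[[1]]
  expect_identical(as.integer(f[4:5]), c(11L, 20L))
})
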