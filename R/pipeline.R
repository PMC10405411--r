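#' Default pipeline configuration
#'
#' One list drives the whole simulate-align-detect run; every stochastic
#' stage derives its own stream from the single `seed` with
#' [deriveSeed()]. Depths are chosen so a default run finishes in minutes
#' on one CPU while giving every detector comfortable signal.
#'
#' @param seed integer run seed.
#' @param outdir output directory.
#' @return named list of parameters; see the entries themselves.
#' @export
defaultRunConfig <- function(seed = 1L, outdir = tempfile("dicerscope_run")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    hairpin = list(arm = 275L, loop = 79L),
    replicon = list(length = 477L, perSiteMutationRate = 0.03,
                    accessibility = 0.01, nMolecules = 2000L,
                    productsPerMolecule = 10L),
    dicer = list(sizeWeights = c(`20` = 0.1, `21` = 0.6, `22` = 0.3),
                 loopLeak = 0, strandEmission = 0.5,
                 backgroundFraction = 0.3),
    depths = list(hairpinReads = 40000L, genomeSrnaReads = 60000L,
                  rnaseqReads = 200000L, deReadsPerRep = 50000L),
    deReplicates = 3L,
    deFoldChanges = c(HAV1 = 3, CUG1 = 4, PLN2 = 0.25, PLN3 = 0.3),
    thresholds = defaultThresholds(),
    boundaryWindow = 20L,
    maxMismatch = 1L
  )
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file.
#' @return a configuration list as from [defaultRunConfig()].
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  cfg <- modifyList(cfg, user)
  if (!is.null(cfg$dicer$sizeWeights)) {
    w <- unlist(cfg$dicer$sizeWeights)
    names(w) <- names(cfg$dicer$sizeWeights)
    cfg$dicer$sizeWeights <- w
  }
  cfg$deFoldChanges <- unlist(cfg$deFoldChanges)
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full simulate-align-detect pipeline
#'
#' Stages: build the minigenome, hairpin and replicon; simulate the sRNA
#' library (hairpin products, genomic dsRNA products, replicon products and
#' degradation background); simulate stranded RNA-seq for two conditions;
#' align everything to the combined reference (genome + hairpin +
#' replicon); then detect: size histogram, hairpin stem fraction and loop
#' boundaries, per-locus antisense calls with a confusion matrix against
#' the planted truth, and a differential-expression summary. All stage
#' outputs are written under `config$outdir`; identical config and seed
#' give byte-identical outputs.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()].
#' @return (invisibly) a list with the report lines and every stage result.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  dicer <- .stage("config", do.call(DicerModel, cfg$dicer))

  mg <- .stage("minigenome",
               buildMinigenome(defaultMinigenomeSpec(), seed = deriveSeed(seed, 1L)))
  hp <- .stage("hairpin",
               buildHairpin(cfg$hairpin$arm, cfg$hairpin$loop,
                            seed = deriveSeed(seed, 2L)))
  rp <- .stage("replicon",
               RepliconModel(length = cfg$replicon$length,
                             perSiteMutationRate = cfg$replicon$perSiteMutationRate,
                             accessibility = cfg$replicon$accessibility,
                             seed = deriveSeed(seed, 3L)))

  # --- simulate the sRNA library -------------------------------------
  genomeChar <- as.character(genomeSequences(mg))
  transcripts <- .stage("background pool", {
    g <- genes(mg)
    tr <- substring(genomeChar[as.character(seqnames(g))],
                    start(g), end(g))
    minus <- as.character(strand(g)) == "-"
    tr[minus] <- .revcomp(tr[minus])
    setNames(tr, mcols(g)$gene_id)
  })
  hpSim <- .stage("hairpin sRNA",
    simulateDicerProducts(hp, dicer, cfg$depths$hairpinReads,
                          seed = deriveSeed(seed, 10L),
                          backgroundPool = transcripts, idPrefix = "hp"))
  gsSim <- .stage("genomic sRNA",
    simulateGenomeSrna(mg, dicer, cfg$depths$genomeSrnaReads,
                       seed = deriveSeed(seed, 11L)))
  diSim <- .stage("replicon sRNA",
    simulateRepliconReads(rp, dicer, cfg$replicon$nMolecules,
                          cfg$replicon$productsPerMolecule,
                          seed = deriveSeed(seed, 12L)))
  # hairpin background reads carry transcript-space provenance (they are
  # degradation of genome transcripts); ids stay distinct across sources
  srna <- .stage("sRNA library",
                 combineReadSets(hpSim$reads, gsSim, diSim))
  librarySize <- length(srna)

  refs <- c(genomeChar,
            hairpin = as.character(transcriptSequence(hp)),
            replicon = as.character(rp@sequence))
  aln <- .stage("sRNA alignment",
                alignReads(srna, refs, maxMismatch = cfg$maxMismatch))

  hist <- .stage("size histogram",
                 sizeDistribution(aln, c(17L, 24L), librarySize))
  hpLen <- 2L * cfg$hairpin$arm + cfg$hairpin$loop
  if (librarySize > 0L && nrow(aln[aln$reference == "hairpin", ]) > 0L) {
    frac <- .stage("hairpin fraction",
                   hairpinFraction(aln, hp, librarySize))
    prof <- .stage("hairpin profile",
                   fivePrimeProfile(aln, "hairpin", hpLen,
                                    sizeFilter = 20:22))
    bounds <- .stage("loop boundary",
                     scanBoundary(prof, hp, cfg$boundaryWindow))
  } else {
    frac <- c(total = 0, mapped = 0)
    bounds <- data.frame(edge = c("left", "right"),
                         boundary = NA_integer_, p_value = NA_real_,
                         p_adj = NA_real_, direction = NA_character_,
                         n_scanned = 0L, stringsAsFactors = FALSE)
  }

  # --- stranded RNA-seq + antisense calls ----------------------------
  rna <- .stage("RNA-seq",
                simulateRnaseq(mg, cfg$depths$rnaseqReads,
                               seed = deriveSeed(seed, 20L)))
  rnaAln <- .stage("RNA-seq alignment", alignReads(rna, refs, 0L))
  cov <- .stage("coverage",
                strandedCoverage(rnaAln, chromosomeLengths(mg)))
  calls <- .stage("antisense calls",
                  callGenome(aln, genes(mg), cov, max(librarySize, 1L),
                             cfg$thresholds))
  truth <- plantedTruth(genes(mg))
  confusion <- table(planted = truth[calls$locus], called = calls$class)

  # --- differential expression ---------------------------------------
  de <- .stage("differential expression", {
    reps <- cfg$deReplicates
    countList <- list(); conds <- character(0)
    for (r in seq_len(reps)) {
      rs <- simulateRnaseq(mg, cfg$depths$deReadsPerRep,
                           seed = deriveSeed(seed, 30L + r))
      countList[[paste0("ctrl", r)]] <- countGenes(alignReads(rs, refs, 0L),
                                                   genes(mg))
      conds <- c(conds, "control")
    }
    for (r in seq_len(reps)) {
      rs <- simulateRnaseq(mg, cfg$depths$deReadsPerRep,
                           seed = deriveSeed(seed, 40L + r),
                           profile = cfg$deFoldChanges *
                             mcols(genes(mg))$baseline_expression[
                               match(names(cfg$deFoldChanges),
                                     mcols(genes(mg))$gene_id)])
      countList[[paste0("induced", r)]] <- countGenes(alignReads(rs, refs, 0L),
                                                      genes(mg))
      conds <- c(conds, "induced")
    }
    cm <- countMatrix(countList, conds)
    expressed <- rowSums(cm$counts) > 0
    res <- nbWaldTest(cm$counts[expressed, , drop = FALSE], cm$conditions)
    list(countMatrix = cm, results = res)
  })
  sig <- filterSignificant(de$results)
  nUp <- sum(sig$log2FC > 0); nDown <- sum(sig$log2FC < 0)

  # --- write outputs --------------------------------------------------
  out <- function(f) file.path(cfg$outdir, f)
  .stage("outputs", {
    writeReference(mg, out("genome.fasta"))
    writeAnnotation(mg, out("annotation.gff3"))
    writeReference(setNames(DNAStringSet(as.character(transcriptSequence(hp))),
                            "hairpin"), out("hairpin.fasta"))
    writeReference(setNames(DNAStringSet(as.character(rp@sequence)),
                            "replicon"), out("replicon.fasta"))
    writeReads(srna, out("srna.fastq"))
    writeProvenance(srna, out("srna_provenance.tsv"))
    writeReads(rna, out("rnaseq.fastq"))
    writeAlignments(aln, out("srna_alignments.tsv"))
    writeCoverage(cov, out("rnaseq_coverage.tsv"))
    hdf <- data.frame(length = as.integer(names(hist$counts)),
                      count = as.numeric(hist$counts))
    write.table(hdf, out("size_histogram.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bounds, out("boundary_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (exists("prof", inherits = FALSE))
      writeProfile(prof, out("hairpin_profile.tsv"))
    write.table(calls, out("antisense_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeCallsBed(calls, out("antisense_calls.bed"))
    write.table(de$results, out("de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  report <- c(
    "# dicerscope pipeline report",
    sprintf("seed: %d", seed),
    sprintf("sRNA library: %d reads, aligned weight %.1f", librarySize,
            sum(aln$weight)),
    sprintf("hairpin stem fraction: %.4f of library, %.4f of mapped",
            frac["total"], frac["mapped"]),
    sprintf("size histogram (17-24 nt): %s",
            paste(sprintf("%s:%.0f", names(hist$counts), hist$counts),
                  collapse = " ")),
    sprintf("loop boundary (left): pos %d, p_adj %.3g",
            bounds$boundary[bounds$edge == "left"],
            bounds$p_adj[bounds$edge == "left"]),
    sprintf("loop boundary (right): pos %d, p_adj %.3g",
            bounds$boundary[bounds$edge == "right"],
            bounds$p_adj[bounds$edge == "right"]),
    sprintf("replicon reads emitted: %d",
            sum(provenance(srna)$substrate == "replicon")),
    "antisense calls:",
    sprintf("  %s: %s", calls$locus, calls$class),
    sprintf("antisense recovery: %d/%d loci match the planted truth",
            sum(calls$class == truth[calls$locus]), nrow(calls)),
    sprintf("differential expression: %d up, %d down of %d tested genes",
            nUp, nDown, nrow(de$results)))
  writeLines(report, out("report.md"))

  invisible(list(report = report, config = cfg, minigenome = mg,
                 hairpin = hp, replicon = rp, librarySize = librarySize,
                 alignments = aln, histogram = hist, fraction = frac,
                 boundaries = bounds, calls = calls, confusion = confusion,
                 de = de, nUp = nUp, nDown = nDown))
}
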