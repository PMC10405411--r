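#' Simulate sRNA reads from a replicase-assisted replicon
#'
#' Each of `nMolecules` replicon copies is first mutated independently at
#' every site with probability `perSiteMutationRate` (replication-driven
#' single-nucleotide variation); only a fraction `accessibility` of the
#' molecules is exposed to Dicer, the rest being shielded inside the
#' membrane-associated replication complexes. Every exposed molecule is
#' treated as a fully double-stranded replication intermediate and yields
#' `productsPerMolecule` duplexes (uniform cut positions, sizes from the
#' \linkS4class{DicerModel}); one strand per duplex is sequenced with
#' probability `strandEmission` for the (+) strand. The number of mutated
#' sites covered by each read is recorded in the provenance.
#'
#' @param model a \linkS4class{RepliconModel}.
#' @param dicer a \linkS4class{DicerModel}.
#' @param nMolecules number of replicon molecules.
#' @param productsPerMolecule duplexes produced per exposed molecule.
#' @param seed integer seed.
#' @param idPrefix read identifier prefix.
#' @return A \linkS4class{ReadSet}; provenance coordinates are 0-based
#'   half-open on the replicon reference, with columns `n_mutations` (sites
#'   mutated within the read) and `molecule`.
#' @examples
#' rm <- RepliconModel(accessibility = 1, seed = 3)
#' rs <- simulateRepliconReads(rm, DicerModel(), nMolecules = 5, seed = 4)
#' provenance(rs)[1:3, ]
#' @export
simulateRepliconReads <- function(model, dicer, nMolecules,
                                  productsPerMolecule = 10L, seed = 1L,
                                  idPrefix = "di") {
  stopifnot(nMolecules >= 0, productsPerMolecule >= 1)
  refChar <- as.character(model@sequence)
  L <- nchar(refChar)
  set.seed(seed)
  exposed <- which(runif(nMolecules) < model@accessibility)
  if (!length(exposed)) return(ReadSet())
  bases <- c("A", "C", "G", "T")
  out <- vector("list", length(exposed))
  for (i in seq_along(exposed)) {
    m <- exposed[i]
    sites <- which(runif(L) < model@perSiteMutationRate)
    mol <- refChar
    if (length(sites)) {
      cur <- strsplit(mol, "")[[1]]
      for (s in sites) cur[s] <- sample(setdiff(bases, cur[s]), 1L)
      mol <- paste(cur, collapse = "")
    }
    nP <- as.integer(productsPerMolecule)
    k <- .sampleSizes(dicer, nP)
    if (L < max(k) + 3L) stop("replicon shorter than one Dicer product")
    p <- 2L + as.integer(floor(runif(nP) * (L - k - 1L)))
    emitGuide <- runif(nP) < dicer@strandEmission
    rs <- ifelse(emitGuide, p, p - 2L)
    re <- rs + k
    plus <- substring(mol, rs + 1L, re)
    seqs <- ifelse(emitGuide, plus, .revcomp(plus))
    nm <- vapply(seq_len(nP), function(j)
      sum(sites > rs[j] & sites <= re[j]), integer(1))
    out[[i]] <- list(
      seq = unname(seqs),
      prov = data.frame(
        read_id = sprintf("%s_m%04d_%04d", idPrefix, m, seq_len(nP)),
        substrate = "replicon",
        start0 = as.integer(rs), end0 = as.integer(re),
        strand = ifelse(emitGuide, "+", "-"),
        n_mutations = nm, molecule = m, stringsAsFactors = FALSE))
  }
  seqs <- unlist(lapply(out, `[[`, "seq"), use.names = FALSE)
  prov <- do.call(rbind, lapply(out, `[[`, "prov"))
  rd <- DNAStringSet(seqs)
  names(rd) <- prov$read_id
  ReadSet(rd, prov)
}
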