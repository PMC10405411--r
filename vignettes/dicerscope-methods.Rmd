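---
title: "Detecting plant Dicer signatures in an RNAi-depleted yeast: models and methods"
author: "dicerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plant Dicer signatures in an RNAi-depleted yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicerscope)
```

## The biological setting

Budding yeast has lost its RNA-interference machinery: no Dicer, no
Argonaute, no RNA-dependent RNA polymerase. Expressing a plant Dicer-like 4
(DCL4) endonuclease in this background isolates a single activity --
dicing -- from everything that normally surrounds it. Whatever 20-22-nt
small RNAs appear in a sequencing library of such cells were made by the
heterologous enzyme, and their properties report directly on which cellular
and viral RNAs fold into, or anneal into, double-stranded substrates.

Three substrate classes carry distinct, detectable signatures:

* **An inverted-repeat hairpin transcript.** Two complementary arms around
  an intron loop fold into a near-perfect double-stranded stem. Dicing
  converts the stem into 20/21/22-nt duplexes; the single-stranded loop is
  spared, so sRNA coverage collapses abruptly at the stem/loop border.
* **A replicase-assisted replicon.** A subviral defective-interfering RNA
  amplified by a viral replicase lives inside membrane-associated
  replication complexes. Although it is double-stranded-like, it is
  physically shielded, so it yields almost no sRNAs -- and those it does
  yield carry the single-nucleotide variants that replication introduces.
* **Sense/antisense co-transcription.** Overlapping transcription of both
  genomic strands (annotated antisense partners, convergent readthrough,
  or unannotated antisense transcripts) creates perfect dsRNA in vivo;
  dicing it leaves strand-symmetric 21/22-nt peaks at the locus.

The package implements both sides of each signature: a generative model
that simulates reads with ground-truth provenance, and the detectors that
recover the signature from reads alone. All detection runs on the read
sequences; provenance is used only to score the detectors in tests.

## The Dicer product model

A product duplex of size $k \in \{20, 21, 22\}$ cut at stem position $p$
occupies $[p, p+k)$ on the guide strand and, through the pairing map
$i \mapsto L-1-i$ of a hairpin of length $L$ (or a 2-nt shift on a linear
duplex), the passenger occupies the window displaced by exactly 2 nt --
both 3' ends protrude 2 nt, the chemical hallmark of RNase III products.
The model's parameters, all on `DicerModel`:

| parameter | default | meaning |
|---|---|---|
| `sizeWeights` | 0.1 / 0.6 / 0.3 | probability of a 20/21/22-nt product; 21-nt dominant, 22-nt second |
| `overhang` | 2 nt (fixed) | 3' overhang of both strands |
| `loopLeak` | 0 | probability a cut is drawn from the loop-permissive distribution |
| `strandEmission` | 0.5 | probability of sequencing the (+)-sense strand of a duplex |
| `backgroundFraction` | 0.3 | non-Dicer degradation reads, lengths uniform on 17-24 nt |

Cut positions are uniform over the double-stranded region: the data the
model emulates show processing "in a highly comparable fashion" across the
stem, and no hotspot structure is assumed. `loopLeak` interpolates between
hard loop exclusion (0: no product interval ever intersects the loop,
enforced exactly, not just in expectation) and uniform processing of the
whole construct as if the loop were stem (1). The latter is the null
hypothesis of the boundary test, which is why the parameter is defined as
a mixture over cut distributions rather than literally as "probability of
overlapping the loop": at `loopLeak = 1` a literal reading would
concentrate products at the loop and manufacture a boundary where the
null needs none.

Background degradation reads are drawn from *other* expressed transcripts
(the minigenome's genes in a full run; a seeded decoy pool in hairpin-only
simulations), never from the hairpin itself: degradation background in a
real library comes from the cellular transcriptome at large, and a
hairpin-only background would sit mostly inside the stem and masquerade
as Dicer signal.

## The hairpin and its boundary statistic

`buildHairpin(arm, loop, seed)` builds arm + loop + reverse-complement(arm).
The analyses use a 275-nt arm and a 79-nt loop, giving the 629-nt
transcript of the inducible silencing construct; the arm length is exposed
as a parameter because only the combination of total length and loop
length pins it down.

Detection proceeds from a stranded 5'-end positional profile of the
aligned reads. At a candidate boundary $b$ with window $w$ (default 20 nt,
about one product length), the 2x2 table
$\{(\text{counts in } [b-w,b)), (\text{counts in } [b,b+w)); (w, w)\}$ is
tested two-sided with Fisher's exact test. The reference row of $w$
pseudo-positions per window encodes the equal-production expectation with
deliberately small mass, which makes the test conservative at high depth:
only near-total positional collapses -- the stem/loop border -- reach
significance, while the mild depth fluctuations of a deeply sequenced
uniform region do not. `scanBoundary()` evaluates every position within
$\pm w$ of each annotated loop edge, reports the minimum-p position per
edge, and Bonferroni-corrects over the positions scanned.

Two properties calibrate the statistic, both computed by the test suite
and the acceptance script: with a hard loop boundary and 20,000 stem reads
the scan localizes both edges within 5 nt of the annotation in at least
95 of 100 seeded replicates (the best split sits 2-3 nt inside the stem
because 5' ends of loop-adjacent products stop short of the border by
construction); under uniform processing (`loopLeak = 1`, 200 replicates)
the corrected rejection rate at $\alpha = 0.05$ stays within the nominal
10%.

A read is counted as stem-derived only if its whole interval lies inside a
stem arm, matching duplex provenance; its 5' end alone is not enough.
Because the denominator of the published "fraction of the library" is
ambiguous, `hairpinFraction()` reports the fraction of total library reads
and of mapped weight side by side. Square-root scaling of profile plots is
presentation only and never touches stored counts.

## The aligner

Reads of 15 nt and up are placed on both strands of every reference at the
minimal achievable mismatch count up to 1 (best-stratum semantics: any
perfect placement suppresses all 1-mismatch placements). All placements of
the best stratum are reported and weighted $1/(\text{number of
placements})$, so every aligned read contributes total weight 1 -- the
property that makes histograms, profiles and locus counts conserve reads.
Exact placements come from hashed $k$-mer lookup; the 1-mismatch stratum
uses the pigeonhole principle (one half of the read must match exactly)
with candidate verification. Both passes are exhaustive at these reference
sizes, and the suite checks placement-set identity against a brute-force
scan over every offset and both strands. Ties are ordered
(reference, start, strand) for reproducibility.

Multi-mapping matters here: the two arms of a perfect inverted repeat are
each other's reverse complement, so every stem read has exactly two
placements (one per arm, opposite strands) at weight 1/2, and reads from a
multicopy repeat element split their weight across the copies. Adapter
trimming is exact-prefix (at least 8 nt) because the reads are synthetic;
error-tolerant trimming is deliberately out of scope.

## The synthetic minigenome

`defaultMinigenomeSpec()` plants every locus archetype the antisense
classifier must recognize on two chromosomes (12 kb + 8 kb, 13 genes):
two tandem gene/antisense pairs overlapping by 700 nt on opposite strands,
one convergent pair with a 150-nt intergenic gap bridged by readthrough,
one gene with unannotated antisense transcription at fraction 0.2, a
repeat element in three identical copies, and three neutral genes. Gene
sizes (0.8-1 kb), expression levels (1-4 reads per transcript copy) and
the 150-nt gap are ordinary yeast-scale choices; the neutral genes' gap
to their convergent neighbours is kept above the 300-nt readthrough
threshold so the locus classes stay cleanly separable by construction.

`simulateGenomeSrna()` turns every doubly-transcribed region into a Dicer
substrate: pair overlaps, readthrough windows (gap plus 150 nt into each
convergent gene, down-weighted by the readthrough fraction 0.3), hidden
antisense gene bodies (weighted by their antisense fraction), and repeat
copies up-weighted tenfold to reproduce the massive retroelement-derived
sRNA signal. Stranded RNA-seq reads follow a multinomial over expression
times length, with readthrough genes elongating 30% of their transcripts
across the gap and hidden-antisense genes emitting opposite-strand reads
at their configured fraction.

What the generator does *not* emulate -- sequencing errors, ligation and
PCR bias, expression bursting, partial complementarity, RNA secondary
structure beyond the designed hairpin -- bounds what passing tests show:
they demonstrate that the detectors recover the signatures the generative
model encodes at realistic depths, not that they are robust to every
artefact of a real library.

## Antisense locus classification

Per locus, 21- and 22-nt alignment weights are assigned by 5'-end
containment (avoiding double counting at overlapping loci), split
sense/antisense relative to the annotated gene strand, and normalized to
ppm of the sRNA library. Strand symmetry is $2\min(s,a)/(s+a)$. The
cascade then asks, in order: annotated opposite-strand overlap with
symmetric sRNA (annotated pair); a convergent neighbour within 300 nt
whose intergenic gap carries antisense RNA coverage (readthrough);
antisense RNA-seq coverage at an unannotated locus (novel antisense);
otherwise none. Defaults -- 5 ppm antisense sRNA, symmetry 0.2, 1 read/nt
antisense RNA, 300-nt gap, half the gap covered -- are explicit knobs, not
reconstructions of unpublished cutoffs; they are deliberately permissive
floors, and every rule requires the antisense sRNA floor, which makes
`none` calls monotone in `minPpm`. Repeat loci are the designed negative
control: loud, symmetric sRNA but no antisense transcription, so they must
classify `none`.

## Differential expression

The count matrix uses 5'-end containment on the matching strand; reads
resolving to more than one gene (repeat multireads) are discarded as
ambiguous, which mirrors the multiread problem of real pipelines and is
why repeat copies carry no counts. The test itself is a deliberately
simplified median-of-ratios + NB Wald pipeline: per-gene method-of-moments
dispersion from the pooled within-condition variance, floored at the
experiment-wide median dispersion; fold change of normalized condition
means with pseudo-count 0.5; Wald variance $\mu \Sigma s_j^{-1}/n^2 +
\alpha\mu^2/n$ per condition mean; two-sided normal p; Benjamini-Hochberg
across genes. Size factors are standardized to median 1 so that rescaling
one sample moves only that sample's factor.

The median floor is the one place the implementation departs from a
purely gene-wise estimator: with three replicates per condition the pooled
variance has four degrees of freedom, and genes whose variance is
under-estimated by chance would otherwise inflate the Wald statistic far
into the tail. Flooring at the typical dispersion of the experiment
restores calibration (at most 1% of 2,000 null NB genes at dispersion 0.1
reach adjusted p < 0.05) without shrinking genuinely high dispersions and
without touching the dispersion-known limit, where the floor is the
numerical constant 1e-8. In that Poisson limit the Wald p agrees with an
exact conditional-binomial oracle to within 0.02 on a 50-gene grid of
mean counts 250-2000 -- the regime the significance filter targets; below
roughly 100 counts per replicate the discreteness of the exact test
dominates and the normal approximation parts company with it, one reason
the filter requires baseMean > 50 in the first place.

Significance uses the fixed thresholds adjusted p < 0.05, baseMean > 50
and |log2 fold change| > 0.585 (fold change 1.5). Effect-size recovery is
checked in a low-dispersion regime (0.005 at mean 1000, 3 vs 3) chosen to
represent isogenic cultures under controlled induction, where a true
fourfold change must come back as log2FC = 2 +- 0.2 for at least 95 of
100 genes. `computeDdct()` supplies the qPCR-side arithmetic:
relative expression $2^{-\Delta\Delta C_t}$, so $\Delta\Delta C_t = 1$ is
the twofold-knockdown regime.

## The replicon scenario

`RepliconModel` defaults to a 477-nt sequence, a per-site substitution
probability of 0.03 per replicated molecule (the simplest generative
reading of a 3% single-nucleotide variation frequency; the alternative
per-molecule reading would not reproduce the observed per-read mismatch
load), and Dicer accessibility 0.01 -- replication complexes shield all
but a hundredth of the molecules. Each exposed molecule is diced as a
linear duplex. Two consequences are checked end to end: at equal molecule
counts the replicon yields at least fiftyfold fewer sRNA ppm than a fully
exposed hairpin, and strictly fewer unique sRNA sequences; and because
mutated molecules seed the reads, a 21-nt read carries at least one
variant with probability $1 - 0.97^{21} \approx 0.47$, which is why the
aligner's 1-mismatch stratum exists at all.

## Numerical and design notes

* Coordinates are 0-based half-open in every tabular interface (alignment
  tables, profiles, provenance, BED); annotation lives in `GRanges`
  (1-based inclusive) and GFF3 is written 1-based inclusive, so an
  internal `[10, 20)` prints as `11..20`.
* One integer seed drives a run; stages derive decorrelated streams with
  `deriveSeed()` (all arithmetic below 2^53, results below 2^31).
* FASTQ qualities are constant maximal and never consulted.
* Boundary-scan ties resolve to the first (leftmost) minimum-p position;
  alignment ties order (reference, start, strand).
* Degenerate inputs: an arm too short for one product is an error unless
  the library is pure background; `n = 0` requests return empty, typed
  objects; an all-zero sRNA library yields zero histograms and all-`none`
  calls rather than an error.
* Problem sizes used by the shipped checks -- 10,000 duplexes for
  geometry, 1,000 reads against 2 kb for the aligner oracle, 100 + 200
  replicates for boundary power and null, 1e5 sRNA + 2e5 RNA-seq reads
  for locus recovery -- were chosen as the smallest sizes at which the
  binomial/Bonferroni arithmetic above has its stated resolution.

## Known limitations

The aligner is exhaustive, not indexed for genome-scale references; BAM
emission, gapped alignment and quality-aware scoring are out of scope.
The DE module fits no covariates and performs no independent filtering or
outlier replacement. The classifier assumes the annotation it is given;
it validates antisense transcription, it does not assemble transcripts.
Dataset-level published figures that depend on the original sequencing
libraries (library-wide ppm totals, genome-wide differential gene counts)
are outside what a synthetic minigenome can or should reproduce.
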