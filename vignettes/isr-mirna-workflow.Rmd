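---
title: "Finding ISR-associated plant miRNAs from small RNA and degradome data"
author: "mirISR maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Finding ISR-associated plant miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question

Beneficial root-colonising rhizobacteria such as *Bacillus velezensis*
FZB42 prime plants systemically against foliar pathogens -- induced
systemic resistance (ISR).  A standard design for finding the microRNAs
that mediate this priming compares three treatments: the ISR-inducing
bacterium, a mutant strain that has lost the inducing ability, and a mock
control, each with replicate small RNA libraries from leaves.  A miRNA that
responds to the inducing strain *specifically* -- differentially expressed
both against the control and against the non-inducing mutant, in the same
direction -- is an ISR candidate.  Candidates are then corroborated on
three independent axes: defense-related cis-elements in their pri-miRNA
promoters, degradome (PARE) evidence that their predicted target mRNAs are
actually sliced, and the functional coherence of those targets (GO
enrichment, a miRNA-target-term network).

`mirISR` implements that whole workflow as a tested R package, together
with a synthetic-data generator that plants a known answer into every
input, so each stage can be verified end to end without any external
download.

## Pipeline stages and the models behind them

### Read cleaning and collapsing

`cleanReads()` removes the 3' adapter by its best leftmost prefix match
(minimum overlap 6 nt, error rate 0.1) and discards reads with mean Phred
quality below Q20, reads containing N, post-trim lengths outside 18--30
nt, and exact blocklist matches (the stand-in for rRNA/tRNA/sn(o)RNA
removal).  None of these thresholds comes from a published value; they are
conventional small RNA-seq practice and all are exposed as arguments.
`collapseTags()` reduces the cleaned streams to unique tags with
per-library counts; every count is conserved (`raw = clean + discarded`,
collapsed counts sum to clean counts), and the tests assert this.

### miRNA identification

Tags are assigned to reference matures 5'-anchored: the shared prefix must
match with at most 0 mismatches (configurable) and the length difference
may be at most 2 nt, reflecting the 3' heterogeneity of real miRNA reads.
Families follow the `miR<number>` prefix of miRBase-style names; novel
identifiers form singleton families.

Novel candidates are called from unassigned, sufficiently abundant tags
(default total count at least 5) mapped exactly to the genome on both
strands.  Around each hit two windows (20/160 and 160/20 nt) are folded
and a candidate is accepted when the mature tag sits on one arm of a
single stem with at least 16 paired bases, the trimmed precursor is
58--250 nt, the hairpin pairing fraction is at least 0.55, and a
star-compatible tag (2-nt 3' overhang, tolerance 1 nt) exists or the star
region is unexpressed.  These thresholds are conventional plant-miRNA
criteria; the folding backend is either the built-in Nussinov base-pair
maximiser (minimum loop 3, G:U allowed) or ViennaRNA's RNAfold when the
executable is on the PATH (`backend = "auto"` prefers RNAfold; the backend
used is recorded per candidate).

Two structural caveats are worth knowing.  First, a perfect inverted
repeat is strand-symmetric, so a hairpin locus is rediscovered from both
strands; deduplication is therefore strand-blind and keeps the candidate
with the larger total tag support inside the precursor, which resolves the
strand correctly because 3'-heterogeneity reads only map to the true
strand.  Second, the structural criteria alone are not a perfect filter
against random sequence: about one random high-count tag in ten sits on a
genuine 16-bp stem by chance (measured over seeded trials with both
backends).  In practice the abundance threshold does most of the filtering
-- scattered background fragments essentially never reach five identical
copies -- and the fixture tests assert exact recovery of the planted
loci with zero extras.

### Differential expression and candidate selection

Counts are normalised as transcripts per million (`count / library total x
1e6`).  The test itself is a two-proportion random-sampling z-test on
replicate-pooled counts: with $\hat p_1 = C_1/N_1$, $\hat p_2 = C_2/N_2$
and pooled $\hat p$,

$$ z = \frac{\hat p_1 - \hat p_2}
            {\sqrt{\hat p (1-\hat p)(1/N_1 + 1/N_2)}} $$

referred two-sidedly to the standard normal.  $M$ and $A$ (log2 ratio and
mean of the pseudocounted normalised proportions, pseudocount 0.5) are
display quantities only.  Selection is on raw $p < 0.05$; BH q-values are
reported alongside for stricter use.  Candidates are the intersection of
the two contrasts (treatment vs control, treatment vs mutant) filtered to
the repressed direction in both; the direction filter can be disabled.

Three statistical properties deserve explicit statement:

* **Calibration holds under the test's own sampling model.**  With
  Poisson/binomial counts the measured type-I error at $\alpha = 0.05$ is
  0.050 over 10,000 null tests, and the test agrees with Fisher's exact
  test within a factor of two for pooled counts of at least 10 outside the
  extreme tail ($p \ge 10^{-3}$); below that the normal tail approximation
  deviates more, as expected of a large-sample approximation.
* **It is anticonservative under biological overdispersion.**  The
  synthetic generator draws counts from a negative binomial (dispersion
  0.1 by default) precisely so this is visible: pooled proportion tests
  inflate type-I error roughly by $1 + \phi\mu$ at large counts (measured
  ~0.59 at $\alpha = 0.05$ under default depth).  This is a faithful
  property of the re-specified method -- it is why replicate-aware NB GLMs
  exist -- and the reason the calibration and exact-recovery experiments
  in the acceptance tests run at dispersion 0, the model the test assumes.
  Under the default overdispersion the planted repressed miRNAs are still
  always recovered; the false positives it admits are handled downstream
  by the direction-plus-intersection filter and degradome support.
* **Proportions are compositional.**  Repressing a sizeable slice of the
  miRNA pool in one condition pushes every other proportion up in that
  condition, so spurious calls under repression are biased toward the
  "up" direction -- another reason the "down in both contrasts" filter is
  effective.

`ddctFoldChange()` provides the standard $2^{-\Delta\Delta C_t}$
relative-quantification companion for qPCR confirmation of candidates.

### Promoter extraction and cis-element scanning

Pri-miRNA promoters follow a three-branch orientation/distance rule, with
the distance defined as the intergenic gap between the pri-miRNA 5' end
and the nearest boundary of the upstream gene (the only anchoring under
which the first branch yields a non-degenerate region for gaps between
0.4 and 2.4 kb):

| geometry | promoter |
|---|---|
| same direction, gap < 2.4 kb | from 400 bp past the gene's 3' end to the pri-miRNA 5' end (gap 1000 gives 600 bp) |
| opposite direction, gap > 4 kb | from the pri-miRNA 5' end to the gap midpoint (gap 5000 gives 2500 bp) |
| everything else | 2 kb upstream, clipped at the chromosome edge |

Opposite-direction gaps of 2.4--4 kb are deliberately left to the default
branch -- the rule set does not claim them -- and flagged via the reported
branch label.  Overlapping loci and gaps of at most 400 bp fall back to
the default branch with a warning.  Coordinates are 1-based inclusive
GRanges throughout, the Bioconductor convention; BED export converts at
the boundary.

`scanMotifs()` reports all IUPAC-aware exact occurrences of the element
library on both strands (minus-strand hits at forward offsets).  The
shipped library (TCA element for salicylic acid, CGTCA motif for methyl
jasmonate, TC-rich repeats for defense/stress) is an editable TSV --
configuration, not an assertion about any catalogue.

### Targets, degradome mapping and categories

`scoreDuplex()` implements plant-style complementarity penalties: WC 0,
G:U 0.5, mismatch 1, each bulged nucleotide 1, everything doubled at
miRNA positions 2--13, minimised over all placements of at most one
single-nucleotide bulge on either strand.  `findTargets()` scans every
transcript window (widths within 1 nt of the miRNA) and keeps scores of at
most 4.0.  The predicted cleavage site sits opposite miRNA position 10 --
the canonical slicing register; the degradome check uses a +/-1 window to
absorb the 10/11 ambiguity, and both are configurable.  A random 21-mer
against a random 1-kb transcript produces a hit at this threshold in fewer
than 1 in 20 pairs (measured 0/300).

`mapDegradome()` piles tag 5' ends on transcripts by exact 20-nt prefix
match.  `categorizeCleavage()` assigns the standard five degradome support
classes given the site abundance `a`, the profile maximum and the median
over positions with at least one tag: category 0 (unique global maximum at
the site), 1 (tied maximum), 2 (`1 < a <` max, above the median), 3 (same
but at or below the median -- ties at the median read "higher than"
strictly), 4 (`a == 1` below the maximum), else unsupported.  The
"more than one peak" wording of category 1 is read as more than one
position attaining the maximum, the standard convention.  Cross-condition
agreement is a set intersection of supported (category at most 3) pairs,
mirroring the DE-contrast intersection.

### Enrichment and network

`enrichTargets()` is an upper-tail hypergeometric test per annotated term
with BH correction; the universe defaults to all genes in the supplied
flat annotation (no ontology-graph propagation -- a documented
limitation) and can be restricted to expressed genes.  Pathway tables
reuse the same code path, so no separate KEGG client is needed or
provided.  `buildNetwork()` assembles the typed miRNA-target-term graph
(edges `targets` and `annotated-to`, no orphan term nodes) and
`exportNetwork()` writes SIF or GraphML for Cytoscape.

## What the synthetic data emulate -- and what they do not

`makeGenome()` plants, on one synthetic chromosome: hairpin precursors
(mature + loop + inverted repeat, 60--244 nt, within the 58--247 nt range
reported for plant pri-miRNA hairpins) for both known and novel loci;
upstream genes cycling through all six promoter geometries; cis-elements
written into the promoters (with incidental motif occurrences scrubbed, so
planted motifs are provably the only hits); a transcriptome with embedded
perfect target sites; and a GO table in which one term annotates exactly
the true target set.  `simulateSrnaLibraries()` draws per-miRNA counts
(NB or Poisson) with the repressed set divided by the repression factor in
the treatment only, emits 5'-anchored reads whose lengths follow the
configured distribution (default: 88% mass in 20--24 nt, 24-nt mode),
adds ~4% star-strand reads, 10% random genomic background, the 3' adapter,
and a fixed handful of low-quality and N-containing reads so the cleaning
filters have true positives.  `simulateDegradome()` piles
Poisson(`degradomeSignal`) tag 5' ends at each true cleavage position over
per-position background noise.

Real data differ in ways these fixtures deliberately do not model:
sequencing error, 5'-end heterogeneity, imperfect (bulged) miRNA/star
duplexes, repeat-derived multi-mapping, rRNA/tRNA fragment classes beyond
a generic background pool, spliced transcripts, and genuine biological
variation beyond a single dispersion parameter.  Passing the fixture tests
therefore demonstrates that the algorithms implement their stated rules
and recover a planted signal under the stated noise model -- not that any
particular biological dataset will yield the same counts.

## Problem sizes and numerical choices

The reference study conditions are 3 conditions x 3 replicates at 1e5
reads per library, 50 known + 8 novel loci on a 300-kb chromosome and 60
transcripts -- large enough that every stage sees realistic multiplicity,
small enough that the full pipeline runs in about two minutes.  Unit tests
use a 12-locus, 8k-read version of the same design.  Ties in tag ordering
break lexicographically; ties in known-miRNA assignment break by fewest
mismatches, then smallest length shift, then reference order; duplicate
target alignments merge keeping the best score, then the ungapped, then
the leftmost alignment.  Degenerate inputs (empty libraries, zero-count
contrasts, empty networks) are first-class tested cases rather than
errors, except where the contract demands an error (zero-total libraries
in TPM, malformed FASTQ records, which are reported with their record
index).

## Known limitations

The DE stage is intentionally the paper-faithful pooled proportion test,
with the anticonservativeness under overdispersion described above; users
with replicate-rich designs should treat the BH q-values as the minimum
and consider NB GLM tools for inference.  Degradome mapping is
exact-prefix against the supplied transcriptome (no spliced or genomic
mapping).  Novel-miRNA calling uses expression plus structure only -- no
conservation analysis, no folding-energy randomisation test.  GO
enrichment is flat, without true-path propagation.
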