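---
title: "Repeatome profiling from low-coverage reads: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeatome profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(repeatome)
```

## The problem

A genome's repetitive fraction — LTR retrotransposons, DNA transposons,
satellite DNA and the ribosomal DNA arrays — can be characterized without
an assembly, from low-coverage shotgun reads alone. At a genomic coverage
well below 1x, reads from single-copy sequence rarely overlap each other,
while reads drawn from a repeat family overlap abundantly in the family's
sequence space. Clustering reads by pairwise similarity therefore
partitions them into repeat families, and each cluster's read count
divided by the total analyzed reads estimates the family's genome
proportion. `repeatome` implements this procedure end to end, together
with the downstream steps that turn clusters into biological objects:
reconstruction of full-length elements from long reads, classification of
5S rDNA tandem arrays, and cross-species divergence statistics.

## Read clustering model

Two reads are *similar* when a local alignment on either strand reaches
90% identity over at least 55% of the shorter read's length. Identity is
defined as matches divided by alignment columns, gaps counting as
mismatches, which makes the threshold unambiguous. Clusters are the
connected components of the similarity graph.

The published repeat-clustering tools use a graph community detection
step inside components; we deliberately do not re-implement it, because
only the similarity and size thresholds are part of the published
contract. Connected components are the honest simplification, and its
consequences are visible in our own simulations: a family whose copies
diverge near the identity threshold can split into more than one cluster.
The abundance accounting is robust to this because clusters of one repeat
are aggregated (by annotation, or in validation by the simulator's
manifest) before proportions are compared — the same grouping a
practitioner applies when reading a cluster table.

Candidate read pairs come from shared canonical minimizers
(k = 13, window 5, so any shared exact 17-mer guarantees a shared
minimizer) and are verified by banded Smith–Waterman around the shared
seed's diagonal, with an exact full-matrix check for borderline results.
On sets of a few hundred reads the resulting partition is tested for
equality against brute-force all-vs-all evaluation of the similarity
predicate; on large inputs exactness is heuristic, which is the standard
trade-off of seeded candidate generation.

Reported ("top") clusters are those holding at least 0.01% of the
analyzed reads; contig assembly is attempted for clusters of at least 5
reads. Clusters are joined into superclusters when at least `min_links`
(default 3; the linking rule itself is plumbing, the threshold
configurable) mate pairs straddle them — typically re-joining the LTR and
internal-region clusters of one element.

## Contig assembly and element reconstruction

The highest-depth contig of a cluster is built by iterative mapping:
starting from the most k-mer-central read, member reads are mapped at
relaxed identity (75%, so a family's mutually diverged copies stack on
one reference), the per-column majority is called, and ends grow by read
overhangs while at least 2 reads agree on the extension. Extension
therefore stops near element boundaries, where each genomic copy runs
into different flanking sequence — a deliberate boundary guard rather
than a limitation.

Full elements are then reconstructed from long reads: the contig is
searched against the long-read set (seeded local alignment, both strands,
Karlin–Altschul-style significance; the top 20 hits by significance are
kept, mirroring standard practice of working from the 20 best hits); on
each hit read the matched interval is extended to the element boundaries
by diagonal-run analysis of the word-match matrix (word size 10, at least
3 consecutive matching words per run, run groups supported by fewer than
25 matched bases are trimmed from the ends so chance word matches cannot
drag a boundary outwards); copies are flagged full when terminal repeats
are present and the length reaches 90% of the modal copy length. The
consensus is a per-column majority over a star alignment anchored on a
scaffold copy chosen near the upper length quartile (fragments are
subsequences of the full form, so the scaffold must come from the long
end; the quartile guards against rare over-merged outliers). Columns with
a gap majority are removed; exact ties become IUPAC codes, which also
makes the consensus invariant to the input order of copies. mafft is
available as a pluggable aligner (`method = "mafft"`) for indel-rich copy
sets; the internal star alignment is the default because it is
deterministic and dependency-free. Consensuses can be polished by
iterative short-read mapping (majority base at positions covered by at
least 3 reads, no indels introduced, at most 3 rounds or convergence).

Protein domains (GAG, PR, RT, RH, INT, CD, transposase) are annotated by
six-frame translated local alignment against a user-supplied domain
peptide set under BLOSUM80, hits chained left-to-right without overlap;
the resulting domain order is the basis for element classification, and
elements assembled in reverse complement are flipped when the majority of
domains lie on the minus strand. Terminal repeats are detected directly:
direct repeats of at least 100 bp at 80% identity are an LTR pair,
inverted repeats of at least 10 bp a TIR pair, neither a truncated
element.

## 5S rDNA arrays

The 5S gene is reconstructed by mapping short reads to a seed gene at
relaxed identity (75%, admitting diverged genes) and majority-calling the
pileup; the mapped fraction of all reads is the abundance proxy used for
cross-species comparison. The complete monomer (gene + non-transcribed
spacer) comes from long reads with at least two gene hits: the interval
from one gene start to the next is a monomer candidate, candidates near
the modal length are aligned and majority-called, and the modal spacer
length defines the NTS.

Array organization is classified per read from hit geometry alone, with
the gene scanned at significance 1e-4 (scoring +1/−3 with linear gap −4;
under this scheme a monomer at ~45% divergence genuinely falls below the
threshold, which is how pseudogenized copies disappear from dotplots):

* **regular** — at least 5 monomers, no major gap, read longer than
  6000 bp;
* **potentially regular** — the gap condition holds but the read is
  ≤ 6000 bp or carries only 2–4 monomers (the 2–4-monomer case on long
  reads is reported as a separate subclass so the strict three-way counts
  remain recoverable);
* **pseudogenic** — at least one major gap between monomers;
* **sparse** — a single monomer.

A *major gap* is operationalized as consecutive monomer starts more than
1.5 periods apart (`gap_frac = 0.5` of the monomer length), configurable;
the published account defines it only visually. Overlapping hits are
merged keeping the more significant one, preventing double counting at
tandem junctions. Every emitted call stores its geometry, so the label is
re-derivable — an invariant the test suite checks call by call. NTS
length variants are flagged when a period deviates more than 20% from the
modal period, and elongated spacers are tested for internal tandem
duplication by off-diagonal word-match runs, the mechanism that produces
long-NTS variants in the first place. Control-region coordinates on the
gene (A-box, intermediate element, C-box) default to canonical plant 5S
internal-promoter positions — defaults, not measured values — and are
user-replaceable.

## Comparative statistics

The abundance matrix has two layers: `relative_share` (reads of repeat r
in species s over all reads clustered for r; rows sum to 1) and
`within_genome` (the same counts over the species' total analyzed reads).
Sequence divergence uses the Kimura 2-parameter distance,
`d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`, over pairwise-deleted columns
(gap and ambiguity handling changes n, P and Q, so it is stated
explicitly); saturation raises an error rather than returning a number.
The estimator is cross-checked in the tests against an independent
implementation (`ape::dist.dna`) and against direct evaluation of the
closed form. Heatmap ordering is average-linkage clustering on the
distances, a purely presentational choice. Tajima's relative-rate test
counts columns where exactly one ingroup lineage differs from the
outgroup and compares the two counts by chi-square on 1 degree of
freedom.

## The simulator and what passing tests mean

The synthetic-data module is the validation instrument: it plants repeat
families with known coordinates, divergences and array labels, and its
manifest is the oracle for every recovery statistic. Background sequence
is i.i.d. at GC 0.38 (plant-like); planted copies diverge by
substitutions with a 2:1 transition:transversion ratio so the K2P
machinery is exercised; indels in planted copies are off by default.
Pseudogenization is operationalized as hyper-mutation at 45% divergence
plus inserted spacers of 1–2 monomer lengths: 15–30% divergence, though
visually "degenerate", is still comfortably detectable by a sensitive
local aligner, so the default hyper-divergence is set far beyond the
detection threshold to reproduce the below-threshold behaviour that
defines pseudogenic arrays. At least one spacer always separates two
detectable monomers, so the mode's hit geometry is guaranteed.

Short reads are 100 nt, paired, substitution errors only (1% default);
long reads are log-normal in length, truncated to 500–72,000 bp, with an
indel-dominated error model at 12% by default — a configurable stand-in,
since no error profile was available for the long-read chemistry being
emulated.

Simulation scales are chosen to respect the method's operating regime:
clustering validation uses a 100-Mb genome with 100,000 read pairs
(0.2x coverage). Low coverage is not incidental — at coverages
approaching 1x, background reads overlap each other and the similarity
graph of single-copy sequence percolates, which breaks the clustering
premise for any implementation of it. Three families at 10%, 5% and 1%
(LTR element, TIR transposon, tandem satellite) are recovered within
±20% relative error across five seeds. Consensus-fidelity validation
plants 30 copies of a 4.6-kb LTR element at 5% per-copy divergence and
demands ≥ 98% identity of the reconstruction; its long reads are
simulated error-free so the statistic isolates biological copy
divergence, the quantity the consensus must average out — long-read
sequencing error is a separate axis, handled by the configurable error
model and the short-read polishing step, and reconstruction quality under
heavy indel noise is not claimed by these tests. Array classification
uses 50 reads per organization class with well-separated parameters
(regular at 2% divergence, pseudogenic at 45% plus spacers) and demands
perfect precision and recall; on real data, intermediate divergences
will blur these classes, which is precisely why every call's geometry is
exported for inspection.

What the synthetic data does *not* emulate: real base composition and its
local heterogeneity, element age structure and nested insertions,
chimeric reads, coverage biases, and organellar contamination beyond a
planted contaminant set. Passing tests therefore demonstrate correctness
of the algorithms under their stated assumptions, not performance on any
particular real library.

## Numerical choices and degenerate inputs

* Alignment scores: clustering verification +1/−1 with linear gap −2;
  nucleotide database search +1/−2; monomer scanning +1/−3, gap −4.
  Significance is Karlin–Altschul-like, `E = K m n exp(-lambda S)`, with
  lambda solved from the scoring scheme at uniform base composition and a
  fixed calibration constant K — it approximates but is not identical to
  BLAST E-values, which is why thresholds are configurable.
* Ties: cluster ids are assigned by decreasing size then first
  appearance; annotation ties break by higher identity, longer span, then
  lexicographic name; consensus column ties become IUPAC codes; top-hit
  ties break by read id so rankings are permutation-stable.
* Degenerate inputs raise errors rather than guessing: empty read sets,
  subsampling beyond availability, arrays without periodicity, K2P under
  saturation or with fewer than 20 comparable columns.
* Coordinates are 0-based half-open throughout (BED convention), strands
  `+`/`-`.

## Known limitations

Connected-component clustering cannot separate families that share
homologous domains at above-threshold similarity; superclusters make the
merge visible rather than preventing it. The contig assembler targets
high-copy families and will stall on coverage dips (by design, at
boundaries); reconstruction then relies on the long-read step. E-values
are calibrated approximately, so absolute significance thresholds should
be treated as tunable rather than exchangeable with BLAST's. The 2–4
monomer "potentially regular" subclass on long reads is a reporting
extension; the strict three-way accounting is preserved alongside it.
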