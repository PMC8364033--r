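---
title: "Metapangenomic inference on stratified microbial communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapangenomic inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metapang)
```

## The problem

Uncultivated marine lineages are sampled as single-cell amplified genomes
(SAGs) and metagenome-assembled genomes (MAGs): incomplete, fragmented
drafts in which any single genome is a poor representative of its
population. `metapang` implements the inference chain that turns a
collection of such drafts plus depth-resolved metagenomes into an
ecological description of the lineage:

1. **Population binning.** Pairwise average nucleotide identity (ANI) over
   all drafts; genomes clustering above the conventional 95% species/
   population boundary are merged into one *population genome*.
2. **Gene-catalog dereplication.** Each population's pooled genes are
   reduced to a non-redundant catalog (95% nucleotide identity over at
   least 90% of the shorter gene, both strands) so a function is counted
   once per population however many drafts carry it.
3. **Pangenome.** All-vs-all protein alignment across catalogs; weak
   partial matches are removed by the *minbit* heuristic (pair bitscore
   over the smaller self-bitscore, threshold 0.5); Markov clustering (MCL,
   inflation 10) yields orthogroups, classified as core (present in every
   population genome), singleton (one population), clade-specific or
   shared, and ordered by Ward linkage on Euclidean distances between
   frequency vectors.
4. **Read recruitment.** Metagenomic reads from each depth are assigned to
   their closest catalog gene when they align at ≥ 80% identity over
   ≥ 70% of the read; mean per-base coverage per gene is aggregated to
   orthogroups and population genomes. Populations with no mapped read
   anywhere are discarded as locally irrelevant.
5. **Ecotypes.** The average-linkage ANI tree over population genomes is
   cut at 80% into subclades; scaled depth profiles are averaged within
   subclades, and subclades with adjacent peaks whose profiles correlate
   at ≥ 0.8 merge into one *ecotype* — a genomically coherent group
   occupying one depth zone. Pathway-level profiles (mean over member
   orthogroups, scaled 0–1 per pathway) are clustered the same way
   (Ward/Euclidean) to expose depth-structured metabolism.

Every stage is driven by explicit thresholds collected in
`threshold_config()`; the numbers above are its defaults.

## Alignment kernels

All stages share two Smith–Waterman local-alignment kernels (C++, affine
gaps: a length-*k* gap costs `open + k * extend`). Nucleotides score
+2/−3 with gap 5/2; proteins use BLOSUM62 with gap 11/1. Bitscores follow
the Karlin–Altschul form `(lambda * S - ln K) / ln 2` with the standard
gapped parameters for those settings (nucleotide λ = 0.625, K = 0.41;
protein λ = 0.267, K = 0.041). Percent identity counts matches over
aligned residue pairs (gap columns excluded from the denominator), the
convention the 80%/95% thresholds are calibrated against; query coverage
is the aligned span over the full query length, which makes the 70% read
filter meaningful. N never counts as a match, and X is scored neutrally.

Deterministic tie-breaks: the forward strand wins score ties; recruitment
resolves equal candidates by identity, then alignment length, then lowest
gene index; dereplication resolves by identity, then alignment length,
then earliest representative.

The batch entry points (fragment ANI, recruitment, protein graph,
dereplication) use exact k-mer seeding — 13-mers for nucleotides, 5-mers
for proteins — to select candidates and a window around the best diagonal
for the dynamic program. Seeding is an acceleration, not an approximation,
in the regimes where the thresholds operate: a 95%-identity gene pair
shares hundreds of 13-mers, an 80%-identity read dozens, and a
minbit-0.5 protein pair always shares 5-mers. Each seeded path has an
`exact = TRUE` escape hatch, and the test suite asserts seeded and
exhaustive results are equal on realistic fixtures. The single-pair
kernels are verified cell-for-cell against an independent R dynamic
program and against `Biostrings::pairwiseAlignment` on hundreds of random
pairs.

## Fragment ANI

`compute_ani()` is fragment-based (ANIb-style): the query genome is cut
contig-by-contig into consecutive 1020-bp fragments (trailing remainder
kept), each aligned to the whole subject; fragments are accepted at
≥ 30% identity and ≥ 70% fragment coverage, the directional ANI is the
mean identity of accepted fragments, and the symmetrized ANI averages the
two directions. A pair with no accepted fragment in either direction is
*missing*, not 0, and missing values are treated as distance 100 by the
clustering (conservative non-merging). Directional asymmetries are
reported (`max_directional_diff` attribute) and are below one point for
complete genomes at moderate divergence.

Local alignment trims mismatch-dense fragment ends, which biases identity
upward slightly; measured against communities whose true divergence is
known exactly (substitution positions recorded), the bias stays within
±1 percentage point across 1–20% divergence and grows to ~1–2 points
near 25%, which does not move any decision made at the 95% or 80%
boundaries.

## MCL numerical choices

The orthogroup clustering adds self-loops at each node's maximum incident
weight (1 for isolates), column-normalizes, and alternates expansion
(matrix squaring) with inflation (entrywise power 10). Entries below 1e−5
are pruned *after* each column rescaling — pruning raw inflated values
would annihilate near-uniform columns (0.25^10 ≈ 1e−6) and dissolve
every balanced clique into singletons. Iteration stops when the matrix
changes by less than 1e−8 (maximum 200 iterations; non-convergence
returns the current state with a warning and a flag). Clusters are read
off as attractor systems; nodes are assigned to the system receiving most
of their flow, ties to the lowest cluster id, so the output is always a
partition. A dense, pruning-free reference implementation lives in the
test helpers and agrees with the package on a seeded family of small
weighted graphs.

## The synthetic community generator

Real SAG/MAG collections with matched metagenomes are too large and too
uncontrolled to validate an inference chain against; `evolve_genomes()`
therefore plants the structure the chain is supposed to recover and the
tests measure recovery exactly.

**Evolution model.** Ancestral core gene families are generated once as
random codon sequences (start codon, no internal stops); each subclade
ancestor applies half the inter-subclade pairwise divergence, each genome
half the intra-subclade divergence, so the *pairwise* divergence between
genomes matches the design parameter. Substitution counts are exact
(`round(d/2 × length)` distinct positions per branch), which makes truth
identity computable by direct position-wise comparison
(`truth_identity()`) — the alignment-free oracle every ANI test uses.

Coding substitutions are 70% synonymous (one per codon, standard genetic
code), the rest uniform among non-stop alternatives. This emulates
purifying selection and is load-bearing: under a uniform model, 30%
nucleotide divergence drives protein identity to ~55% and minbit below
0.5, so no orthogroup would span subclades — the planted pangenome
structure would be unrecoverable by construction rather than by failure
of the method. A side effect of concentrating changes on third codon
positions is repeated-hit saturation: nominal pairwise divergence 0.30
realizes ~0.24 (ANI ≈ 75–77%).

**Genome layout.** Core and subclade-specific genes are colinear on
shared contigs, separated by inherited 25-bp spacers that mutate at the
same rates; singletons sit on one extra contig per genome, mirroring
accessory islands while keeping shared regions free of structural
differences. `apply_incompleteness()` drops an exact fraction of genes
per genome (default 0.54, typical of draft SAG/MAG completeness) and
reassembles contigs.

**Abundance and reads.** Each subclade follows a Gaussian depth-abundance
curve (peak depth, width, amplitude); the default community places four
subclades at 25, 125, 500 and 1000 m over a seven-depth grid spanning
25–1000 m. Reads (single-end, 100 bp, 1% substitution error, constant
quality) are drawn per depth with probability proportional to subclade
abundance times genome length, uniform start positions, equiprobable
strands; every read's origin genome, position and gene are recorded.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: indels and rearrangements (alignments in real
drafts gap; here coordinates stay colinear), chimeric reads and quality
variation, horizontal transfer (orthofamily boundaries are clean),
strain-level abundance variation within a population, and uneven
sequencing depth across samples. Because each sample draws a fixed read
count, coverage measures *relative composition*: a subclade alone in its
depth zone shows a plateau, not a peak, across that zone — the ecotype
peak-depth oracle therefore works in composition space and treats depths
within 5% of the compositional maximum as one plateau.

## Ecotype delineation choices

The merge rule operationalizes "genomic similarity plus congruent depth
distribution": subclades come from the 80% tree cut (members of one
subclade cohere above 80% ANI); profiles are scaled per population so
any positive rescaling of a population's coverage — sequencing effort,
genome size — cancels; multiple dates per depth average before
delineation; merging proceeds best-correlated adjacent pair first and
repeats until no adjacent pair reaches the threshold (default 0.8), so
lowering the threshold can only merge more (ecotype count is
non-increasing). Peak depth is the argmax over the depth grid with ties
to the shallowest depth. Constant profiles correlate 1 only with an
identical profile, else 0. Both the cut (80%) and the merge threshold
(0.8) are exposed arguments; the defaults reproduce, on the planted
analog, the field's familiar outcome of two genomically distinct
subclades sharing one mid-depth zone merging into a single ecotype while
surface and deep subclades stay separate.

## Problem sizes

The shipped analysis and the acceptance checks run at desk scale, chosen
so the whole chain (simulation → binning → pangenome → recruitment →
ecology) completes in minutes on one core: 12 genomes × ~36 genes
(~430 gene records) for the default community, 20,000 reads per depth
across 7 depths, 200 genes / 40 families for the dereplication oracle,
50,000 reads for the recruitment accuracy check, and 10 genomes in 5
subclades for the ecotype analog. All randomness flows from one master
seed through named substreams per stage, so any stage can be rerun in
isolation and full pipeline runs are byte-identical.

## Known limitations

- Dereplication follows greedy longest-first semantics; the member
  *partition* is order-invariant, but which equal-length gene represents
  a family can depend on id ordering (ties broken lexicographically).
- Fragment ANI at divergences beyond ~20% inherits the local-alignment
  end-trimming bias (≤ ~2 points); decisions at the 95% and 80%
  boundaries are unaffected, but reported ANI values in the 70s are
  slight overestimates.
- Recruitment is best-hit-only; multi-mapping reads are not split
  fractionally, so paralog-rich catalogs would attribute shared coverage
  to one member. The specificity tests show this is negligible when
  catalog genes are mutually < 80% identical.
- The protein graph uses one alignment per pair (symmetric scoring makes
  the two directions equal); composition-based score adjustments and
  E-values are out of scope.
- Single-end reads only; paired-end, quality-aware alignment and
  RPKM/TPM-style normalizations are out of scope.
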