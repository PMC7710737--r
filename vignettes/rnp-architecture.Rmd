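---
title: "Resolving lncRNA RNP architecture: methods and design notes"
author: "rnparch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving lncRNA RNP architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnparch)
library(IRanges)
```

# The problem

Large architectural long noncoding RNAs — the ~19-kb XIST/Xist transcript
being the canonical case — fold into compact modular domains, and distinct
protein assemblies dock onto distinct domains. No single assay resolves this
organisation: paired-end RIP captures long-range contacts through incidental
proximity ligation, psoralen crosslinking (PARIS) maps base-paired duplexes,
eCLIP/irCLIP map protein footprints at nucleotide resolution, and meRIP maps
m6A methylation. `rnparch` implements the computational layer that ties
these together on one coordinate system, plus a synthetic-data layer that
plants known truth so every stage can be validated quantitatively.

All analyses run in *mini-genome* (mature transcript) coordinates: reads are
assumed to have been aligned upstream to the intron-free transcript
sequence. Coordinates are 1-based closed inside R (the IRanges convention);
files on disk use the ordinary 0-based half-open BED conventions, converted
at the I/O boundary. Read alignment itself, duplex-group assembly from raw
gapped reads, and de novo repeat discovery are upstream of this package;
alignments, DG tables and repeat annotations are inputs.

# Coordinate model

`TranscriptModel` holds exon blocks (genomic), plus repeat-unit and domain
annotations (transcript coordinates). `buildTranscriptSeq()` concatenates
exon sequence, reverse-complementing minus-strand genes — strand is handled
at build time only, and all downstream analysis is strand-free transcript
space. `liftGenomeToTranscript()` maps genomic intervals through the exon
blocks; because an interval can straddle an intron, the result reports the
bounding span of mapped bases together with the mapped-base fraction, so
callers can filter partial lifts (0.5 is a reasonable threshold; the
default keeps everything and leaves filtering explicit). Cross-species
lifting uses `LiftChain`, an ordered table of equal-width aligned blocks;
bases in chain gaps are dropped, and `liftDgTable()` applies the same rule
to both arms of each duplex group, keeping a group only when both arms lift
with at least half their bases (by default). Block-chain lifting is our
realization of homologous-transcript coordinate transfer; it assumes the
chain is colinear (no inversions), which holds for the transcripts this
package targets.

# Chimeric pairs and long-distance groups

In a lightly crosslinked, sonicated RIP library, both sequenced 31-nt tags
of a pair come from one fragment, so the pair *span* — the inclusive outer
distance `max(tag ends) − min(tag starts) + 1` — follows the fragment-length
distribution, concentrated at 100–400 nt. Ligase joining two crosslinked
fragments produces pairs whose span reflects the *transcript-space distance
between contact points*, often kilobases. The classifier is a single span
threshold, default 1000 nt: far enough above the sonication tail that
essentially no single fragment crosses it, close enough to retain contacts
from 1 kb upward. The boundary is inclusive to "short" (span exactly 1000 is
not chimeric). Classification is symmetric in the two tags.

Long pairs are clustered into long-distance groups (LGs) in the 2-D space
of (5′ tag midpoint, 3′ tag midpoint) by single-linkage clustering under the
Chebyshev metric with link distance 500 nt — implemented as connected
components of the "within 500 nt on both axes" graph, which is exactly the
single-linkage dendrogram cut at that height. Duplicate pairs (identical
coordinates on both tags) are collapsed before support counting, since PCR
duplicates would otherwise inflate support; groups need 5 distinct pairs by
default. Both parameters are configurable: 500 nt matches the visual
discreteness of ligation anchors, and a support of 5 suppresses sporadic
ligations without losing real anchors at realistic chimera rates (at a 2%
chimera rate and 10^5 pairs, each planted anchor collects hundreds of
pairs).

Because tags cover only fragment ends, `extendToFragment()` widens tag1
downstream and tag2 upstream to the average fragment size (default 194 nt)
before footprint comparisons. `lgDgOverlap()` then declares an LG to support
a duplex group when its extended anchors intersect the two duplex arms, in
either arm order.

# Enrichment profiles, clustering, PCA

Profiles are built in 100-nt windows: per-window mean coverage, then the
ratio `(sample + 1) / (input_mean + 1)` against the average of the input
controls (the pseudocount of one read per window keeps zero-input windows
finite), and finally one multiplicative rescale so the 25th percentile of
each profile equals 0.1. Quantiles use the linear-interpolation ("type 7")
definition. Pinning a low quantile equalises non-enriched background across
samples of arbitrary depth — the output is exactly invariant to scaling the
sample library by any constant — while leaving profile *shape* untouched.
An all-zero sample is an error, not a silent flat profile.

Clustering uses 1 − Pearson correlation and average linkage by default, so
samples group by *where* they bind rather than how strongly; Spearman and
Euclidean variants and a `log2` switch are provided (profiles are linear by
default). A constant profile has no defined correlation and is assigned the
maximal distance 2 with a warning. PCA is the SVD of the column-mean-centred
samples × windows matrix, no variance scaling, with the removed mean profile
reported as its own track; variance-explained fractions are the squared
singular values normalised to sum to 1. Components are oriented so that each
one's largest-magnitude loading is positive — a pure sign convention that
makes runs reproducible. Spearman correlation between two profiles uses
midranks and the two-sided t approximation.

# Repeats and motifs

`averageOverUnits()` computes the position-wise mean of a per-nt signal
across equal-width tandem-repeat units, with an optional flank on each side
(units whose flanked footprint leaves the transcript are dropped with a
warning). Typical settings: 24-nt units with 10-nt flanks for a short
repeat, 290-nt units with no flank for a long one; unit coordinates always
come from the annotation, never from internal repeat finding.

`scanMotif()` matches degenerate IUPAC motifs (T≡U) at every overlapping
position — a base matches when the motif position's code set contains it;
the matching is delegated to `Biostrings::matchPattern(fixed = "subject")`,
which implements exactly this semantics, and is verified in the tests
against a brute-force sliding-window oracle. Overlapping matches are
counted; that is the conservative superset when the convention is
unstated. `motifDensity()` counts match *starts* per 300-nt window sliding
by 50 nt, dividing terminal partial windows by their actual width to avoid
edge depression. `meanMotifSpacing()` is sequence length per match — for
the m6A consensus DRACH on a typical transcript, one motif per ~54 nt,
which is the background against which focal methylation stands out.

# Duplex-group overlap and its permutation test

A query DG overlaps the reference set when at least one reference DG
intersects it on both arms (left with left, right with right; arms are
stored sorted). The null model preserves, per DG, its left-arm width,
right-arm width and inter-arm gap, and places the whole unit uniformly at
random along the transcript. Preserving the gap keeps each duplex's
structural length scale — the conservative null for "do two species'
duplexes co-locate", since destroying the gap would also destroy the
long-range/short-range composition of the set. A `freeArms` mode placing
arms independently is available for sensitivity analysis. The p-value uses
the add-one correction `(1 + #{shuffled ≥ observed}) / (n + 1)`, so it is
never zero: at 1000 shuffles the strongest possible result is
p = 1/1001 < 0.001. Which set to shuffle is in principle symmetric; the
query is shuffled here.

Because the overlap fraction is discrete (multiples of 1/n_query) and ties
between shuffled and observed values are common, the null distribution of
this p-value is *super-uniform* (conservative), not exactly uniform. The
calibration tests therefore check validity one-sidedly: the empirical CDF
of null p-values must not exceed the uniform CDF beyond Monte-Carlo error
(one-sided Kolmogorov–Smirnov at α = 0.01). The shuffle itself is checked
for geometry conservation and for uniformity of placement by chi-square
goodness of fit.

# Domain quantification

For predefined domains (m6A domains, insertion-site regions supplied as
BED — they are defined per study, so none are hard-coded), enrichment is the
ratio of within-transcript read fractions,

```
enrichment = ((ip_d + 1)/(ip_total + 1)) / ((input_d + 1)/(input_total + 1)),
```

invariant to each library's depth and robust to overall transcript
expression differences between alleles. Per-allele results are expressed as
`log2(enrichment_allele / enrichment_reference)` with the reference
(wild-type) allele identically 0. Note the normalisation is *compositional*:
raising true occupancy in one domain necessarily lowers every domain's read
fraction, so the expected log2 ratio of an unchanged domain is not exactly
0 but `−log2(W_allele / W_ref)` where `W = L + Σ(fold − 1)·width`; the
recovery tests assert against this closed-form expectation rather than the
naive fold ratio. When all alleles' reads are mapped to the wild-type
transcript, reads from a relocated repeat insertion multi-map back to the
original locus; the `mask` argument removes such an interval from both
tracks and the totals.

# irCLIP sites and clusters

Reverse transcription in irCLIP stops one nucleotide 3′ of the crosslinked
base, so the site is 1 nt 5′ of each read start; reads starting at position
1 (no upstream base) and reads antisense to the transcript are dropped,
each with its own counter. Cluster calling is the shift/extend/intersect/
trim procedure with closed intervals: extend each site ±5 nt, merge
overlapping intervals within a replicate, keep only cross-replicate
intersections, then trim 5 nt from each side; intersections narrower than
11 nt vanish. With extend = trim, two isolated single sites therefore
cluster only where they coincide exactly — an exhaustive offset scan in the
tests confirms this arithmetic. Within-replicate merging before
intersection is our choice (the alternative, intersecting raw extended
intervals pairwise, gives the same clusters for isolated sites but can
fragment dense runs); it is documented and directly exercised by the
worked examples. An optional exact-duplicate collapse (same start and end)
stands in for fastq-level deduplication, which belongs upstream.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of their arguments and a seed (the
caller's RNG state is restored), and their defaults are the study
conditions used throughout the tests and the acceptance script:

- **Transcript**: 19 kb, GC 0.5, tandem repeats overwritten at requested
  positions (e.g. 8 × 24 nt), named domains.
- **RIP pairs**: fragment lengths truncated-normal (mean 200, sd 80,
  min 62 = two 31-nt tags), uniform placement; chimera rate 0.02 with tags
  drawn uniformly within the two arms of planted anchor pairs.
- **IP/input coverage**: input multinomial-uniform; IP multinomial with
  weight `fold` inside planted domains; 50,000 reads per library.
- **DG sets**: random arm/gap geometry; a planted fraction of the query are
  ±10 nt jittered copies of reference DGs.
- **irCLIP**: Poisson(20) reads per planted site starting 1 nt downstream
  of the crosslink, 5% uniform background, two replicates.

These emulate the *statistical structure* the analyses rely on — fragment
geometry, spatially clustered chimeras, domain-structured fold enrichment,
co-locating duplexes, replicated pileups — and deliberately nothing else:
no sequencing errors or quality scores, no crosslinking chemistry or
sequence bias, no multi-mapping ambiguity, no overdispersion beyond
multinomial/Poisson sampling. Passing tests on these data demonstrate that
the algorithms recover planted truth under their stated models; they do not
certify performance on real libraries, where biases and overdispersion
will widen error bars (though not change the estimators' identities).

# Pipeline, determinism, problem sizes

`runPipeline()` executes all stages from one YAML configuration in
dependency order, derives every stage's seed deterministically from the
single top-level seed, and writes a JSON manifest with parameters, package
version and an MD5 checksum of each output; re-running an identical
configuration reproduces every file byte for byte. Missing required fields
(`seed`, `samples`, `transcript`) raise errors naming the field. The
packaged demo configuration covers all eight stages and completes in a few
seconds.

Test and acceptance problem sizes were chosen as the smallest that make the
statistical assertions sharp: 10^5 pairs for chimera recovery (binomial
99.9% interval ±0.0015 around the planted 0.02), 50k reads per library for
domain recovery (per-domain log2 standard error ≈ 0.1, against a 0.3
acceptance band), 10^4 shuffles for conservation/uniformity checks, 200
replicate experiments at 199 shuffles for null calibration, 1000 random
sequences for the motif oracle.

# Known limitations

- LG calling uses dense pairwise distances between long pairs; it is meant
  for the (typical) regime of 10^3–10^4 long pairs per transcript, not
  transcriptome-scale input.
- Lifted intervals report bounding spans, not split sub-intervals, across
  chain gaps; the mapped fraction is the guard against over-interpreting
  sparse lifts.
- Antisense reads are discarded, not flipped: appropriate for sense-only
  transcripts, wrong for bidirectional loci.
- The permutation test conditions on the reference set and the query's
  geometry; it does not model uncertainty in DG calling itself.
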