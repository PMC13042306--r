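---
title: "Containment screening and coverage-weighted LCA classification"
author: "taxsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Containment screening and coverage-weighted LCA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxsift)
```

## The problem and the design

Taxonomic classification of metagenomic assemblies faces two coupled
constraints: reference collections are enormous (so exhaustive
alignment is impractical), and environmental sequences diverge from
their nearest references (so exact k-mer indices lose recall at lower
ranks). `taxsift` implements the two-stage compromise: a cheap,
alignment-free *containment screen* first shrinks the reference set to
a handful of sample-relevant genomes, and only those are aligned and
fed into a *coverage-weighted lowest-common-ancestor* (LCA) vote that
backs off to coarser ranks when the evidence disagrees.

## Containment screening

A reference is represented by a bottom-$s$ MinHash sketch: the $s$
smallest values of a seeded 64-bit hash applied to its canonical
k-mers (a k-mer and its reverse complement hash identically, making
screening strand-agnostic). Containment of reference $A$ in query set
$B$ is estimated by the fraction of sketch hashes present among the
query's distinct k-mer hashes. Because the sketch is a uniform random
sample of $A$'s k-mer space, the estimator's standard error scales as
$\sqrt{1/s}$ — `sketchError(s)` — and the screening test suite checks
the estimate against exact full-set containment under a
$3\sqrt{1/s}$ bound.

Parameter guidance follows the usual genome-size argument: the k-mer
length that keeps the probability of a chance k-mer occurrence at $q$
in a genome of size $n$ is $k = \lceil \log_{|\Sigma|}(n(1-q)/q)
\rceil$ (`optimalKmerSize`). Defaults in the pipeline are $k = 15$,
$s = 1000$, hash seed 42 — the small-genome regime appropriate for the
30–60 kb synthetic references used in validation; sketches built with
different $k$ or seed refuse to be compared.

Two numerical choices deserve a note. Hashes are the 64-bit
MurmurHash3 finalizer of the 2-bit-packed canonical k-mer (XORed with
the seed) truncated to the top 53 bits, so every hash is exactly
representable as an R double and set membership is exact; at
$s \le 5000$ the collision probability in a 53-bit space is
negligible. Second, each screen hit carries an upper-tail binomial
p-value for its shared-hash count, with per-k-mer match probability
$r = 1 - (1 - |\Sigma|^{-k})^{m}$ for a query of $m$ distinct k-mers,
computed via `log1p`/`expm1` because $4^{-15}$ underflows naive
arithmetic.

## Adaptive candidate selection

`adaptiveSelect` starts at a stringent score threshold (0.90), counts
qualifying references (optionally after keeping only the best
reference per species), and lowers the threshold in 0.02 steps until
the count reaches the sample-scaled target
`max(round(3.25 × nQueries), 5)` or the 0.70 floor is reached. Hits
below the floor are never returned. Thresholds are stepped with
integer arithmetic on hundredths, so the ladder
$0.90, 0.88, \ldots, 0.70$ is hit exactly and the recorded final
threshold is always a ladder value; deduplication happens inside the
loop so the target counts species-unique candidates.

One scale question was genuinely open: a raw containment index decays
like $(1-d)^k$ with divergence $d$, so a 0.70 floor on *containment*
would reject any query more than ~2% diverged ($k=15$) even though the
alignment stage comfortably handles 10%. The pipeline therefore
converts containment to a Mash-style identity estimate $c^{1/k}$
(`containmentToIdentity`) before thresholding — on that scale 0.90 and
0.70 correspond to roughly 10% and 30% divergence, matching what the
downstream aligner can use. The selection operation itself is
scale-agnostic (it thresholds whatever score it is given), and
`runPipeline(screenScore = "containment")` restores raw-containment
thresholding.

## Alignment coverage

The classifier consumes PAF records (0-based half-open coordinates;
the first 12 columns; tags ignored). Per (query, reference) pair,
coverage is the length of the **union** of the query intervals divided
by the query length — overlapping alignments are merged, never summed,
so coverage cannot exceed 1 and is invariant to record order and to
splitting an alignment into abutting pieces. A record is an *exact
match* iff it is full-length and mismatch-free
(`nMatches == blockLen == queryEnd − queryStart == queryLen`); this
operational definition is the package's own, chosen so that exactness
is decidable from PAF fields alone. No mapping-quality filter is
applied by default. An optional hook shells out to minimap2
(`asm10` for contigs, `sr` for reads); everything downstream only sees
PAF, so any aligner emitting PAF can substitute.

## The weighted consensus classifier

For a query with at least one exact match, the matching reference's
full lineage is assigned with confidence 1.0 (ties: higher coverage,
then lexicographic reference id). Otherwise each supporting reference
is weighted by `coverage × abundance`, where abundance is the
reference's share of all alignment records in the dataset (the
simplest reading of "frequency in the dataset"; a distinct-query
variant is available via `referenceAbundance(basis = "queries")`).

Descending the rank ladder, weights are accumulated onto the
references' lineage taxids at each rank. The winner at a rank must
descend from the winner at the previous rank — this parent-consistency
rule prevents chimeric lineages assembled from unrelated references —
while the consensus fraction divides the winning weight by the *total*
weight at that rank, so off-lineage evidence still dilutes confidence.
Descent stops at the deepest rank whose fraction is at least
`minSupport` (default 0.5, with ties favouring the smaller taxid for
determinism); the confidence is the product of the recorded fractions,
over reported ranks only — including unreported deeper ranks would
deflate every confident coarse assignment for no informational gain.
With the `>=` rule, two references of equal weight in the same genus
sit exactly at the 0.5 boundary and are reported at species rank with
confidence 0.5; raising `minSupport` to 0.6 moves the same query to
the genus. A query with no alignments, or no rank reaching
`minSupport`, is reported unclassified (confidence 0), never an error.

All alignments of a multi-mapped query contribute weight; no best-hit
filtering is applied. This permissive reading keeps the evidence model
simple and monotone; a best-hit variant would interact with the
abundance term in ways the validation suite could not distinguish at
these problem sizes.

## Profiles and metrics

`profileFromClassifications` turns classifications into a rank-indexed
relative-abundance profile: each query contributes `1/N` (count basis)
or its length share (length basis) to its lineage's taxid at every
rank it reaches; mass of queries that stop above a rank stays
unassigned there, so per-rank sums may be below 1. Metrics over a
prediction/truth pair are computed on the union of taxa with absent
taxa zero-filled: presence precision/recall/F1 at a 0.1% abundance
threshold, L1 total variation (reported without the ½ factor, so
L1 = 2 × Bray–Curtis for normalized profiles; fraction or
percentage-point scale is an explicit argument), Bray–Curtis
dissimilarity, Pearson correlation, per-rank contig accuracy
(unclassified counts as incorrect), and rank-group shares
(species/strain, genus, family, higher/unknown). An empty
predicted-positive set reports precision 0 with an explicit flag; an
empty truth-positive set is an error, since recall is undefined.

## The synthetic community

`generateCommunity` is the package's study condition, not a
convenience: 10 species across 6 genera, the first genus holding 4
close congeners whose genomes are independent 3%-divergent copies of a
shared ancestor (mirroring the sister-species structure — e.g.
*Candida albicans* / *C. dubliniensis* — that makes species-level
classification hard in real gut standards), genomes of 30–60 kb,
log-normal abundances (sdlog 1), and ~150 contigs of 2.5 kb drawn in
proportion to abundance. Contigs are exact substrings; the truth
profile is derived from the same contigs under the count basis, so a
perfect classifier reproduces it exactly. `windowReads` slices contigs
into deterministic 250 bp reads (a final tail is kept iff ≥ 125 bp);
`mutateSequence` applies per-base events (90% substitutions, 10%
indels of geometric mean length 3 — "short indels" made concrete);
`ablateReferences` removes a reproducible fraction of a taxon's
reference sequences. All generators take explicit integer seeds and
save/restore the global RNG state.

What the generator does *not* emulate: sequencing error profiles and
quality scores, assembly artefacts (chimeras, collapsed repeats),
real genome composition (GC skew, repeats, mobile elements), and
databases orders of magnitude larger than the sample. Passing tests
therefore demonstrate the correctness and the qualitative robustness
of the machinery — exact-path recovery, graceful degradation under
divergence, back-off under reference ablation — not field accuracy on
real communities.

## Validation design and problem sizes

The suite runs entirely on generated data at sizes chosen to keep a
full run in tens of seconds on one CPU: 100 reference/query pairs of
5 + 20 kb for the containment bound, the 10-taxon community (~150
contigs, ~1500 windowed reads) for end-to-end recovery,
reads-vs-contigs concordance, a mutation sweep at {0, 10, 20, 30}% and
single-species ablation. Two independent oracles guard the core: a
scalar-path brute-force k-mer hasher checks the rolling sketch
builder, and a from-first-principles re-derivation of the rank-vote
checks `classifyQuery` on random ≤ 6-reference cases. Bray–Curtis is
cross-checked against `vegan::vegdist`.

On the clean community every contig returns its true species at
confidence 1.0 through the exact-match path and the species-rank
Bray–Curtis to truth is 0. Under mutation, species-rank F1 declines
monotonically: screening passes diverged queries down to the ~30%
identity floor, and the `asm10` alignment stage stops producing
alignments beyond ~10–20% divergence, so the loss is gradual rather
than cliff-edged. Removing all references of one congener reroutes its
contigs to the remaining sisters: assignments either back off to the
(correct) genus or name a sister species with visibly reduced
confidence — never a wrong species at confidence 1.0, which is the
operative guarantee of the confidence model.

## Known limitations

- Abundance weighting uses alignment-record frequency, which is
  sensitive to secondary-alignment reporting by the aligner.
- The identity transform $c^{1/k}$ assumes independent point
  mutations; long indels and rearrangements violate it.
- Strain-level resolution exists in the rank ladder but the simulator
  generates no strain nodes, so the strain path is exercised only by
  unit fixtures.
- The screen pools all query k-mers, so a reference contained in *any*
  subset of the sample passes; per-query screening would be stricter
  but quadratic.
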