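# taxsift

Hybrid taxonomic classification of metagenomic contigs and reads:
MinHash containment screening with sample-adaptive candidate selection,
alignment-coverage ingestion (PAF), and a coverage-weighted
lowest-common-ancestor (LCA) classifier with rank-consensus confidence
scores — together with CAMI-style evaluation metrics and a seeded
synthetic-community simulator so the whole pipeline can be exercised
and validated offline.

## Who this is for

Metagenomics practitioners who need per-contig (or per-read) taxonomic
labels plus a rank-wise abundance profile, and tool developers who need
a transparent, fully testable reference implementation of the
screen-align-classify design: large static k-mer indices are replaced
by a cheap containment screen that narrows the reference set *per
sample* before any alignment is attempted.

## The method

**1. Containment screening.** Each reference genome *A* is summarized
by a bottom-*s* MinHash sketch *S(A)*: the *s* smallest 64-bit hashes of
its canonical k-mers. Against the query k-mer set *π(B)* the
containment index is estimated as

```
c_k(A, B) ≈ |S(A) ∩ π(B)| / |S(A)|
```

with standard error ≈ `sqrt(1/s)`. A binomial-tail p-value guards
against chance matches, and a suggested k-mer size for a genome of
length *n* is `k = ceil(log_4(n(1−q)/q))` for an acceptable
random-k-mer probability *q* (k = 15 for a 5 Mb microbial genome at
q = 0.01; k = 20 at 3 Gb).

**2. Adaptive candidate selection.** Starting from a stringent score
threshold of 0.90, the threshold is lowered in 0.02 steps until the
number of qualifying references reaches a sample-scaled target
(~3.25 per query sequence, rounded, minimum 5) or the 0.70 floor is
reached; candidates below the floor are never used. One reference per
species can be retained (species-level deduplication).

**3. Coverage-weighted LCA.** Queries are aligned to the selected
references only (minimap2 `asm10` for contigs, `sr` for reads; any PAF
works). A full-length, mismatch-free alignment assigns the reference's
complete lineage at confidence 1.0. Otherwise each supporting
reference gets weight

```
Weight = Coverage × Abundance
```

(coverage: fraction of the query covered by the union of its
alignments to that reference; abundance: the reference's alignment
frequency in the dataset). Walking the rank ladder from superkingdom
to strain, the weights vote at every rank; the winning taxon's
consensus fraction is recorded, descent stops at the deepest rank
whose fraction stays above the support threshold (default 0.5), and

```
Confidence = Π_i (consensus fraction at rank_i)
```

**4. Evaluation.** CAMI-style scoring against truth profiles and
contig maps: presence precision/recall/F1 at a 0.1% abundance
threshold, L1 total variation, Bray–Curtis dissimilarity, Pearson
correlation of abundances, per-rank contig accuracy, and rank-share
summaries.

## Worked example

```r
library(taxsift)

com <- generateCommunity(nTaxa = 4, contigsTotal = 40, seed = 11)
res <- runPipeline(communityContigs(com), communityGenomes(com),
                   genomeTaxids(com), communityTaxonomy(com))

head(res$classifications, 3)
#>       queryId                                          lineage taxonomicLevel taxid confidence
#> 1  ctg_t9_001 k__Domain1;...;g__Genus1;s__Genus1 species1            species     9          1
#> 2  ctg_t9_002 k__Domain1;...;g__Genus1;s__Genus1 species1            species     9          1
#> 3 ctg_t10_001 k__Domain1;...;g__Genus1;s__Genus1 species2            species    10          1

round(rankAbundance(res$profile, "species"), 3)
#>     9    10    16    22
#> 0.049 0.805 0.073 0.073

presenceMetrics(res$profile, truthProfile(com), "species")
#> species presence P/R/F1: 100 / 100 / 100
brayCurtis(res$profile, truthProfile(com), "species")
#> [1] 0
```

Every contig of the clean community comes back with its true species
taxid at confidence 1 (the exact-match path), so the predicted species
profile matches the truth exactly: Bray–Curtis 0. The abundance vector
reflects the log-normal community structure (taxon 10 dominates with
80.5% of contigs).

A shell entry point wrapping the same functions is installed at
`exec/taxsift` (subcommands `sketch`, `screen`, `select`, `classify`,
`evaluate`, `simulate`, `ablate`).

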