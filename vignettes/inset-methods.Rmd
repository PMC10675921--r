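---
title: "Models and methods behind insetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind insetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insetr)
```

# The screen and its analysis

A lentiviral insertional-mutagenesis fitness screen tags millions of genomic
positions with proviral insertions in a cell population, applies a selective
pressure (prolonged culture or a drug challenge), and sequences the
LTR-genome junctions before and after selection in three biological
replicates per arm. An insertion that disrupts an element required for
fitness is depleted from the surviving population; an insertion that confers
an advantage is enriched. `insetr` implements the downstream analysis:

1. **Insertion-site calling** — from LTR-tagged paired reads (or their
   alignments, consumed as SAM text) to a matrix of unique insertion
   positions by samples.
2. **IACFs** — single *insertions affecting cellular fitness*, called per
   site by a replicated paired test on log-transformed normalized depths.
3. **Clusters and CACFs** — SICER-style enriched/depleted islands per
   replicate, reduced to *clusters affecting cellular fitness* supported by
   at least 2 of 3 replicates, and validated against a random-placement
   null.
4. **Annotation and enrichment** — hierarchical one-category assignment of
   calls to genomic elements, density/depth metrics, odds ratios,
   TSS-distance bins and conservation comparisons.
5. **CAGE validation** — candidate TSSs checked against CAGE tag atlases
   with a composition-matched shuffle null.

All coordinates in the package are 0-based half-open (BED convention);
1-based inputs (SAM, fixedStep WIG) are converted on read. "Overlap" always
means at least one shared base, and an unstranded feature matches either
strand in strand-aware operations.

# Insertion-site calling

Read 2 of a junction library must begin with the 68-nt LTR tag
(`inset_ltr_tag()`). The filter is an exact prefix match — reproducibility
is preferred over sensitivity, since a single mismatch cannot be
distinguished from a chimeric artifact at this read depth — and every base
of both mates must exceed Phred 20 (strict inequality). The tag is trimmed
before alignment, so the insertion position is the first genomic base
upstream of read 2's alignment: `start - 1` on the plus strand, the
alignment end on the minus strand. Pair retention requires unique mapping
(a mapped flag and MAPQ at least 30), a single contig, opposing strands and
an outer span of at most 1,000 bp; each rule is a tunable argument and
rejections are counted by reason. Depths are normalized to counts per
million retained pairs (CPM). CPM keeps every observable nonzero depth far
above the zero floor used next: with a raw-fraction normalization a
singleton site would sit near 1e-8 and *below* the floor, inverting its
ordering against true zeros.

# IACF statistics

Per site, normalized depths are log10-transformed with zeros set to -5, a
floor below any observable nonzero CPM. Three control and three treated
replicates are compared by a paired t test and selected by
Benjamini-Hochberg FDR (default 25%) within the assay system; the testing
universe is every site observed in at least one of the six samples.

The replicate arms carry no natural 1-1 pairing, so the default test forms
all 9 treated-minus-control differences and treats them as a paired sample
with 8 degrees of freedom. Users should know what this buys and what it
costs: the 9 differences share only 6 underlying values, so their sample
standard deviation understates the standard error of the mean difference by
about `sqrt(3)`, and the resulting p-values are anti-conservative — on null
data far more than 25% of sites can pass a 25% FDR. The package therefore
also exposes `pairing = "matched"` (replicate *i* against replicate *i*,
df = 2), which has nominal type-I behavior but little power at three
replicates; the calibration-sensitive tests in the suite use it. This
trade-off is intrinsic to the published design; the cluster-level analysis
below is the robust route and is validated independently.

Zero-variance degenerate cases are resolved explicitly: identical arms give
t = 0, p = 1; a nonzero mean difference with zero variance gets the smallest
representable positive p.

# Cluster calls (islands) and CACFs

Cluster calling follows the SICER design on the raw insertion events (one
record per read, not unique sites): the genome is tiled in 200-bp windows;
a window with `k_t` treatment events is scored by the upper-tail Poisson
probability of `k_t` given expectation
`max(k_c, lambda0) * N_t/N_c`, where `k_c` is the control count in the
window and `lambda0` the genome-wide mean control events per window (the
floor prevents zero expectations). Windows with p at most 0.2 are eligible;
eligible windows separated by at most 600 bp of ineligible windows form an
island; the island p-value is Fisher's combination of its member windows'
p-values; islands are selected by BH FDR at 1%. Depleted islands come from
swapping the two samples' roles. Window size, gap, screen threshold and FDR
are all exposed; bit-identity with any particular SICER release is not
claimed, since only the FDR of the original run is known.

CACFs are connected components of pairwise-overlapping same-direction
clusters drawn from at least 2 of 3 replicates; the CACF interval is the
union of its members, so every supporting cluster is represented.
Opposite-direction clusters never combine. Coordinate-merging CACFs across
systems (strand- and direction-agnostic) yields the unique-CACF count used
in reporting.

**The null that validates the caller is a random-placement simulation**:
the same number of events per sample is redrawn uniformly over the genome
and the full cluster + CACF pipeline re-run (`null_cluster_ratio()`,
default 100 simulations). On the synthetic screen this yields zero
simulated CACFs in essentially every simulation while real planted screens
produce hundreds of clusters — the same qualitative behavior reported for
the original screens. Two caveats worth stating plainly. First, Fisher's
combination over windows *selected* for small p is itself anti-conservative
when the event density is high; the procedure's specificity comes from the
consensus requirement and from the emptiness of the random-placement null,
not from the island p-values being calibrated. Second, because treated
depths are renormalized to constant sequencing depth, planting depletions
makes every neutral position slightly enriched in relative abundance — a
real property of selection screens, which shows up as additional enriched
calls and as some consensus clusters even in an all-neutral pool screen.

# The synthetic screen generator

The generator's defaults define the test-bed conditions: a 2 x 500 kb toy
genome; 10 protein-coding gene models of 5 exons, whose second and fourth
exons are the 20 planted essential elements of 5 kb (fitness multiplier
0.05, i.e. 20-fold depletion); two planted enriched elements (multiplier
5); lncRNA genes, vlincRNAs, promoters, enhancers, insulators, intronic and
intergenic predicted-only exons and a gene-desert zone at least 50 kb from
every gene, laid out deterministically so truth classes never overlap.

Sequencing is modeled as a shared pool of 2,000 unique integration
positions (all samples derive from one transfected population), resampled
multinomially to 10,000 read-level events per sample; treated arms weight
each position by its element's fitness multiplier. The pileup of many reads
per position is the essential realistic feature: junction libraries
sequence each integration to substantial depth, and it is this local depth
that lets the role-swapped window model see depletion at all — with every
event at an independent uniform coordinate, a depleted region's control
counts equal the genome-wide background floor and are statistically
invisible. At these defaults a 5-kb element carries about 50 baseline
events (10 positions at mean depth 5), and 19-20 of the 20 planted
elements are recovered as depleted CACFs.

What the generator does **not** model: lentiviral integration-site sequence
bias and hotspots, PCR duplication structure, chromatin context, copy-number
variation, and real human genome composition. Passing tests therefore
demonstrate the correctness and calibration of the *procedure* under
idealized sampling, not performance on real libraries.

Read emission writes read 2 as the LTR tag plus the genomic sequence 3' of
the insertion point on the event strand and read 1 as the opposing mate
within the span limit, with constant Q37 qualities and an optional
substitution error rate (default 0); a truth SAM of the tag-trimmed
alignments makes the caller testable without an external aligner, and the
round trip recovers 100% of non-edge planted coordinates exactly.

# Annotation, enrichment and conservation

Each position is assigned to exactly one category, the first match in a
fixed order from coding exons down to gene deserts
(`annotation_categories()`); the order is configurable because the rarely
overlapping regulatory classes have no published total order. TSS distance
bins (0-5 and 5-10 kb, up- and downstream, strand-aware) qualify only if a
downstream position is not exonic in that gene; the nearest qualifying TSS
wins. Gene deserts are intergenic positions at least 50 kb from any gene
boundary. Densities are unique positions per megabase of element sequence
(the unit is a package choice; only relative comparisons are meaningful),
and average depths drop positions with at least 10,000 reads as outliers
before averaging. Odds ratios use the standard 2x2 cross-product with an
optional Haldane-Anscombe 0.5 correction on zero cells. Conservation at an
insertion site is the mean of the two immediately flanking bases' scores
("immediately adjacent" is interpreted as the two flanks of the insertion
point); group comparisons across assay systems use a one-sided paired t
test on system-level means.

# CAGE validation

Candidate TSSs are extended by +/-10 bp on their strand (a 21-bp inclusive
window — the arithmetic forces this width), dropped if within 10 bp of an
annotated mRNA TSS on the same strand, and merged into clusters categorized
hierarchically (exon > intron > antisense intragenic > intergenic). For
each real cluster, `factor` (default 20) simulated clusters of identical
width and random strand are placed uniformly within the cluster's region
category, so the per-category composition is preserved exactly;
width-matching removes the trivial width covariate, which the composition
constraint alone would not control. Per-cluster signal is the number of
samples with at least one same-strand tag in the cluster and the summed
normalized abundance `C * 1e7 / T`. Real and simulated sets are compared by
a chi-square test on the detected/undetected table (Fisher's exact on
degenerate tables) and two-sided Wilcoxon rank-sum tests on the full
distributions, zeros included.

# Effect sizes, qPCR and reporting arithmetic

Cohen's d uses the pooled standard deviation; Hedges' g applies the
small-sample correction `1 - 3/(4(n1+n2)-9)`. RT-qPCR triplets impute
missing Ct at the 40-cycle ceiling and drop a single technical outlier more
than 2 Ct from both of its agreeing partners; fold changes from cleaned Ct
values use a paired t over all treated-by-control cross-pairs (up to 36 —
sharing the anti-conservatism discussed for the 9-pair test), and fold
changes limited by the Ct = 40 floor are flagged. The relative-fraction
fold change of a novel isoform multiplies the two fold magnitudes when the
annotated isoform moves down and divides when it moves up; reported folds
round half-up to one decimal, as do all reported percentages.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data:
the full screen at the default conditions above, an exhaustive island
oracle on genomes up to 100 kb, brute-force oracles for BH, the paired
tests, Poisson tails, Fisher's combination and the rank-sum test at n up to
1,000, and a 100-seed random-placement null. The complete suite runs in
well under a minute on one core. Ties in BH share ranks by stable sort
order; island spans are trimmed to their first and last eligible window;
merge operations never join half-open abutting intervals; percentages with
zero denominators are reported as `NA` rather than 0.

# Known limitations

* The cross-pair t tests (9-pair and 36-pair) reproduce the published
  design and are anti-conservative; calibrated error control at three
  replicates requires the matched pairing, which is underpowered. Treat
  single-site IACF lists as a ranking, and rely on CACFs for inference.
* Island p-values combine screened windows and are not calibrated at high
  event density; the random-placement null is the supported specificity
  check.
* The annotation hierarchy resolves overlaps by rank, so category counts
  depend on the configured order wherever regulatory classes overlap.
* SAM is consumed as text at desk scale; BAM/CRAM and tabix indexing are
  out of scope, as is running any external aligner.
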