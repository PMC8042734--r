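---
title: "Profiling and dating transposable-element invasions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and dating transposable-element invasions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teinvasion)
```

## The problem

A transposable-element (TE) family that recently entered a species leaves a
characteristic fingerprint in resequenced strains.  Strains sampled before
the invasion carry only old, fragmented, highly diverged copies of the
family — typically heterochromatic relics of a much earlier wave of
activity — while strains sampled after the invasion additionally carry
full-length copies nearly identical to the family consensus ("canonical"
copies).  Laboratory strains established from wild flies at known dates act
as frozen samples of the populations they came from, so classifying each
dated strain as *absent*, *degraded-only*, or *canonical* and reading the
categories along the time axis brackets the invasion.  The host side of the
story is visible in small-RNA libraries: strains that experienced the
invasion produce abundant piRNAs matching the canonical sequence, with the
10-nt 5′-overlap signature of germline ping-pong amplification, while naive
strains only carry piRNAs matching the degraded fragments — piRNAs that are
too diverged (more than roughly 10% mismatch) to silence the canonical
element.

`teinvasion` implements this entire analysis as a reusable pipeline:
consensus-space TE profiling from short reads, assembly fragment
annotation, three-category strain classification and invasion-window
inference, cross-strain composition statistics (allele-frequency PCA,
pairwise F~ST~, neighbor-joining trees), and the small-RNA analyses.  A
synthetic-data generator with complete ground truth makes every stage
testable without any sequencing download, and an internal micro-aligner
removes the dependency on external mappers.

## The synthetic landscape generator

`simulation_config()` fixes the study conditions; `simulate_landscape()`,
`simulate_dna_reads()` and `simulate_small_rna()` realize them.  The
generator emulates:

* **Canonical copies** — full-length copies at low divergence (default 2%,
  within the 1–5% band typical of recent activity), placed in contig
  interiors (the euchromatin-like compartment).  An optional
  internal-deletion haplotype (`deletion_haplotype = c(start, end,
  frequency)`) plants a shared large deletion in a subset of copies, the
  situation that produces "deletion arcs" in coverage plots.
* **Degraded fragments** — consensus substrings (50 bp lower bound,
  default 100–800 bp) mutated to 10–30% divergence and placed near contig
  ends, emulating centromere-proximal relic copies.
* **Three single-copy genes** (default 1 kb each, named after the
  normalization genes customarily used) providing the coverage denominator
  for copy-number estimation.
* **Reads** — single-end, fixed length, uniform start positions, iid
  substitution errors (default 1%), constant placeholder qualities.  Read
  count is `round(coverage * genome_length / read_length)`.
* **Small RNAs** — piRNAs with uniform lengths on 23–29 nt drawn sense and
  antisense from chosen source sequences, a tunable fraction ρ of antisense
  reads placed at exactly 10 nt 5′–5′ overlap with a sampled sense read,
  and miRNA reads (fixed 22 nt) from a synthetic miRNA reference used for
  normalization.

Divergence is realized as `round(d * L)` substitutions at distinct uniform
positions, so per-copy truth divergence is exact; indels in degraded copies
are off by default (`indel_rate = 0`) to keep truth divergence
well-defined.  Background sequence is iid uniform A/C/G/T — the simplest
null that cannot spuriously align to the consensus below 40% divergence at
reportable lengths.  All three generators restore the caller's RNG state
and are byte-deterministic given the config (including its seed).

What the generator deliberately does *not* model: paired-end inserts, PCR
duplicates, quality-dependent errors, indel-rich degradation, nested
insertions, or piRNA-cluster structure.  Passing tests therefore
demonstrate correctness of the machinery under substitution-dominated
divergence and uniform sampling, not robustness to every artifact of real
libraries.

## The micro-aligner

`align_reads()` is an exact-k-mer-seeded, window-extended glocal aligner:
the full read must align, reference ends are free.  Scoring is match +1,
mismatch −1, affine gaps costing 3 + length, and a flat cost of 25 for
arbitrarily long reference gaps.  The flat long-gap cost is what lets a
read spanning a large internal TE deletion align contiguously with a `D`
operation (it overtakes the affine cost beyond 22 bp, just above the 20 bp
arc-detection threshold); it is implemented with a running row-maximum, so
it costs O(1) per cell in both the seeded aligner and the exhaustive
oracle.  `oracle_alignment_scores()` computes the same objective by full
dynamic programming over every reference position with no seeding — an
independent check used by the test suite, where the seeded path reproduces
the exhaustive score for ≥ 99.9% of 10,000 simulated reads.

Two modes mirror the pipeline's two mapping regimes.  *Genomic* mode keeps
the best alignment when its divergence (mismatches plus inserted bases over
read length) is at most `max_divergence` (default 0.25 — permissive enough
that 10–30% diverged fragments remain mappable at the low end, mirroring
the permissive mapping intent of consensus-space profiling).  *Small-RNA*
mode instead caps mismatches at 2.  Seed length defaults to 11 (genomic)
and 7 (small RNA; by pigeonhole, a 23-nt read with ≤ 2 mismatches always
retains an intact 7-mer).  Ambiguity is the number of co-optimal loci;
ties report the lexicographically first (strand `+` first, then target id,
then leftmost position), so results are deterministic with no RNG.
Divergence uses one fixed denominator convention — aligned read bases, with
insertions counted as mismatches and deletions not — because no single
convention is universal and mixing them is a classic source of silent
incomparability.

Coordinates are 0-based half-open internally and 1-based only at the
SAM/TSV boundary.  SAM text import/export round-trips all alignment fields
(`NM` carries edit distance, `AS` score, `X0` ambiguity).

## TE profiling

`build_te_profile()` summarizes one family in one strain from alignments to
the combined reference (TE consensus plus single-copy genes):

* **Coverage** per consensus position, split into uniquely (ambiguity 1)
  and ambiguously mapped reads.  Reference positions skipped by a deletion
  operation contribute no depth — they feed the arc detector.
* **Variants**: per-site A/C/G/T and small-deletion counts; allele
  frequency is count over site total, so 14 copies with "A" and 6 with "T"
  give frequency 0.7.  A site is flagged as a SNP when a non-consensus
  base reaches `min_count` (2) and `min_freq` (0.1); both thresholds are
  exposed since no canonical values exist.
* **Deletion arcs**: deletion operations ≥ 20 bp aggregated by identical
  breakpoints.  Frequency contrasts supporting reads with gap-free reads
  crossing the two junctions (averaged), because a deletion longer than the
  read length can never be "spanned without the gap" in the literal sense.
* **Copy number** = mean total depth over the consensus divided by the
  mean over genes of each gene's median depth.  The numerator uses total
  (unique + ambiguous) depth because degraded families map ambiguously and
  would otherwise vanish; the per-gene median resists edge effects.  Genes
  with zero coverage are excluded with a warning; all-zero normalization is
  an error.  Low-coverage consensus ends are *not* trimmed before
  averaging; this is recorded here rather than silently changed.
* **rpm** = family reads × 10⁶ / all mapped reads, with ambiguous reads
  contributing 1/ambiguity to family counts (avoiding double counting
  across families) and full weight to coverage displays.

## Classification and chronology

The three-category call is formalized with explicit thresholds
(`classification_thresholds()`) so every call is auditable and
recomputable, rather than read off plots by eye: *absent* below 0.2
copies; *canonical* when copy number recomputed from low-divergence reads
(divergence < 0.10) reaches 0.5 **and** those reads cover ≥ 80% of the
consensus; otherwise *degraded-only*.  The 0.10 read-divergence cut
deliberately matches the sequence-divergence boundary below which piRNAs
can silence a target, and cleanly separates the simulated 1–5% and 10–30%
regimes.  The coverage condition matters: a strain whose low-divergence
reads are confined to one short subregion (a fragment at the low end of
the degraded range) does not become "canonical" on copy number alone.

`infer_invasion_window()` reduces dated calls to an invasion window:
`first_canonical_year` is the earliest canonical year;
`all_canonical_year` the earliest canonical year strictly after every
non-canonical year.  Dated non-canonical strains sampled at or after
`first_canonical_year` are listed as discordant — the stock-contamination
signature — rather than silently absorbed.  Undated strains are classified
but excluded from window arithmetic.  Sampling years are treated as exact
integers; their historical uncertainty belongs in the metadata, not in the
window algebra.

## Fragment annotation

`annotate_fragments()` is a desk-scale seed-and-extend local aligner over
both strands: exact 8-mer seeds clustered by diagonal (clusters of ≥ 2
seeds are extended; substitution-only divergence keeps true seeds on one
exact diagonal), Smith–Waterman extension in a padded window, merging of
same-consensus hits separated by < 50 bp on both sequences, a greedy
overlap filter that suppresses redundant sub-hits, and divergence
recomputed from the final alignment as mismatches over alignment columns.
The seed length of 8 (not larger) is what keeps 100 bp fragments at 30%
divergence detectable: the expected number of intact 8-mers there is ~5,
versus ~2 intact 11-mers whose absence would be common.
`extract_degraded_reference()` then builds the degraded-fragment mapping
target: fragments with divergence strictly above 0.10 and length ≥ 100 bp
("longer than 100 bp" is read inclusively at exactly 100 — the boundary is
biologically immaterial but must be pinned for reproducibility), with
minus-strand fragments reverse-complemented.

## Composition statistics

`build_frequency_matrix()` collects, per strain, the frequency of every
flagged non-consensus allele (a "SNP" here is a variant among dispersed
copies, not an allelic variant at one locus); cells with coverage below
`min_support` are missing, strains with no family coverage are dropped
with a warning, and downstream analyses are complete-case — imputation is
deliberately avoided at this scale.  `transform_and_pca()` applies
`asin(sqrt(x))`, centers columns without variance scaling (the common
default for this transform; scaling is a caller choice), and uses SVD.
`pairwise_fst()` implements the classical per-site estimator
(π~T~ − π~W~)/π~T~ averaged over one window spanning the whole consensus;
an external tool's undocumented extra coverage filters are not imitated.
`nj_tree()` delegates to `ape::nj` with negative branches clamped to zero
and name-ordered labels for deterministic ties.

## Small-RNA analysis

Reads are size-filtered in two inclusive stages (18–36 nt for mapping and
miRNA normalization, then 23–29 nt for piRNA-sized reads), partitioned
across a disjoint reference database (canonical consensus, degraded
fragments, miRNAs, other ncRNA) by best alignment with ≤ 2 mismatches,
with cross-category co-optimal ties split fractionally.  piRNA abundance
is normalized to miRNAs (ppm = per million, ppk = per thousand; ppk =
ppm/1000 exactly).  Degraded-fragment piRNA abundance is summed across the
whole fragment set, matching how a concatenated degraded reference is
customarily counted.

Position profiles index 5′ ends: alignment start for sense reads, the
rightmost aligned base for antisense reads.  The ping-pong histogram is
c~k~ = Σ~p~ sense5(p) · antisense5(p + k − 1) for k = 1..20 — the count of
5′–5′ pairs overlapping by exactly k nt, both end bases inclusive; the
overlap convention is pinned explicitly because an off-by-one here is the
classic ping-pong bug.  Pairs are counted as products of 5′ counts (all
pairs), not minima, which makes z~10~ invariant under integer scaling of
all counts — a property the tests assert.  z~10~ is the position-10
enrichment over the mean and standard deviation of the other 19 bins and
is flagged undefined for single-stranded data (the no-signature case).
Multimapping piRNAs are weighted 1/ambiguity by default, with a flag to
disable.

`divergence_gated_fraction()` checks the silencing-relevance gate
directly: a piRNA passes if its best local alignment to either consensus
strand spans ≥ 90% of the read with mismatch fraction strictly below 0.10.
At 20–30% source divergence, local alignments of 23–29 nt reads collapse
to short high-identity islands and fail the span requirement, which is
exactly the biological point: degraded-fragment piRNAs cannot engage the
canonical element.

## Numerical choices and problem sizes

Deterministic tie-breaks everywhere (lexicographic loci in the aligner,
name-ordered NJ labels); no RNG outside the generator.  Degenerate inputs
are flagged rather than silently propagated: zero-depth sites carry
undefined frequencies, constant matrices yield zero variance fractions
with a flag, single-stranded ping-pong data yields an undefined z~10~,
missing distances are an error instructing complete-case filtering.

The test suite exercises the pipeline at deliberately compact sizes — a
1 kb consensus (600 bp in the chronology sweep), 600 bp genes, 20–30×
coverage, 10⁴ reads for the aligner-oracle comparison and 10⁴ piRNAs per
ping-pong run (both null and signal runs use the same library size) — so
the full suite completes in minutes while each recovery property (copy
number within ±20%, classification without error, planted invasion year,
PC1 separation, ping-pong null/signal behavior, divergence gating) is
still measured from end-to-end runs of the actual machinery, never from
shortcuts.

## Known limitations

The micro-aligner is a stated stand-in for production mappers, not a
re-implementation of any of them; parity with external tools on real data
is not claimed, and the annotator's agreement with full repeat maskers on
real genomes is likewise out of scope.  Copy numbers for heavily degraded
families are underestimates by construction (coverage averaged over the
full consensus), the same caveat that applies to coverage-based estimators
generally.  Real piRNA abundances in specific strains cannot be reproduced
here because they require the original sequencing libraries; the package's
claims are about the machinery, validated against synthetic ground truth.
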