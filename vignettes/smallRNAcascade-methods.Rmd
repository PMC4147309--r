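---
title: "Methods: sequential small RNA annotation and two-library differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential small RNA annotation and two-library differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallRNAcascade)
```

# Scope

`smallRNAcascade` analyses a two-library small RNA sequencing design — one
library per condition, no replicates — of the kind used to compare an
L1-retrotransposon-active cell line against its L1-silenced counterpart. The
pipeline takes raw 36-cycle reads, produces filtered unique-read lists,
assigns them to annotation categories (miRNA mature / mature-star / hairpin,
piRNA, repeat-associated RNA in sense and antisense orientation), normalizes
the per-species counts, ranks differential expression with a conservative
posterior fold change, and aggregates repeat counts by RepeatMasker class
and family.

# Preprocessing

**3' adapter trimming.** Inserts are short (17–31 nt), so a 36-cycle read
runs through the insert into the 3' adapter. The trimmer finds the leftmost
position where the remainder of the read matches the start of the adapter
exactly — either a read suffix equal to an adapter prefix of at least
`minOverlap` bases (default 6), or a full internal adapter occurrence with
trailing bases discarded. Reads with no such match are rejected: with a
known adapter and exact matching, an unmatched read is either longer than
the recoverable insert range or not an insert at all. No 5' trimming is
performed; single-end sequencing starts at the 5' end of the insert.

**Spike-in removal.** When a silencing construct is introduced as an shRNA,
its reads would otherwise count as differential small RNA signal. Removal is
full-length, equal-length, ungapped matching against the spike sequences
with a 1-mismatch tolerance (default). Exact-only matching would leave
1-error copies of an abundant spike in the library; allowing length-changing
matches would risk removing genuine miRNAs, so reads whose length differs
from every spike are always retained.

**Collapsing and filters.** Identical trimmed sequences are collapsed into
unique reads with occurrence counts. Sequences shorter than 17 nt are
removed (all their occurrences), then distinct sequences with a total
library count of 1 ("singletons") are removed — the only reading of a
post-collapse singleton filter that is well defined. A sequence that is both
short and a singleton is accounted as short-removed so that the disposition
ledger (`FilterReport`) partitions the input exactly:
input = adapter-rejected + spike-removed + singletons + short + retained.
This conservation law is a class invariant and is checked on every
construction.

# The sequential miRNA cascade

Reads are classified against three reference sets in a fixed order: mature
miRNAs first, then mature-star sequences, then hairpin precursors. At each
stage, a read's best hits are all (reference, offset) pairs achieving the
minimal mismatch count within the allowance; exactly one best pair is a
*unique* match, two or more equally good pairs (different references, or
different positions of one reference) an *ambiguous* match. Assigned reads
— unique and ambiguous — are removed before the next stage. The order
matters because every mature sequence is a substring of its hairpin: without
sequential removal, mature reads would be re-detected at the hairpin stage
and double-counted. The test suite demonstrates this by running the stages
in reverse and observing hairpin counts inflate.

The mismatch allowance at the miRNA stages is identity-derived:
`floor((1 - 0.9) * L)` mismatches for an L-nt read (2 for a 22-mer),
mirroring a 90% minimum-identity criterion. An alignment-score threshold
used by some mappers is not reproduced — such scores are tool-internal and
not reconstructable from their published descriptions — so identity is the
sole criterion. Alignment is ungapped (indels are not modelled; at these
read lengths a single indel usually destroys the match anyway) and
strand-specific everywhere: reads are never reverse-complemented, and
antisense transcription is represented by a dedicated antisense reference
set rather than by opposite-strand alignment.

Ambiguous counting follows the multi-mapping convention of small RNA
aggregators: an ambiguous read credits its count to every tied reference
(so per-species sensitivity is preserved) but contributes once to
per-category and mapped-read totals (so read accounting stays honest). The
cascade result keeps a second exact conservation law: unique-read counts
over the six categories plus the leftover set equal the input.

# Length-routed piRNA and repeat branches

piRNAs are 24–31 nt, Dicer-independent; repeat-associated small RNAs are
mostly 18–23 nt. The branches therefore split the *full* filtered read set
(not the cascade leftovers — both branches are defined on the trimmed
libraries; a flag `branchFromLeftover` offers the alternative) at a length
boundary: reads strictly longer than 23 nt go to the piRNA branch, the rest
to the repeat branch. The boundary is the one genuinely ambiguous reading
in the source procedure (one description says "less than 23", another
"< 24 nt", while the piRNA side is ">23" in both); the default here keeps
the partition exhaustive — 23-mers go short — and `boundary = 22` gives
the strict alternative. Branch mapping allows up to 2 mismatches,
strand-specific, with the same tie rules as the cascade. Sense and
antisense repeat references are mapped in two independent passes, so a
read may legitimately appear in both outputs.

# Normalization

Each annotation universe (miRNA, piRNA, repeat sense, repeat antisense) is
normalized independently by median-of-ratios: a reference sample is the
per-species geometric mean of the two libraries' counts,
`sqrt(a_i * b_i)`; species with a zero count in either library are excluded
(their reference is zero or undefined); each library's size factor is the
median quotient of its counts to the reference. The median makes the factor
robust to a handful of strongly differential species that would bias
total-count scaling — exactly the situation a strong condition effect
creates. Numerical conventions are fixed for bit-reproducibility: the
median of an even-length list is the mean of the central pair, and if no
species is nonzero in both libraries the factors fall back to 1 with a
prominent warning.

One property worth stating precisely, because the obvious form of it is
false: with a two-sample geometric-mean reference, multiplying library B by
k rescales the reference by sqrt(k), so `sB` scales by sqrt(k) and `sA` by
1/sqrt(k). What is exactly invariant is the factor ratio `sB/sA` (scales by
exactly k) and every normalized B/A ratio — i.e. all fold changes. The
tests assert these at 1e-9.

# Posterior generalized fold change

With one library per condition there is no dispersion to estimate, and raw
fold changes of low-count species are dominated by sampling noise. The
estimator therefore reports a conservative fold change from the posterior
of the log2 ratio: with a Poisson likelihood for counts at rate
`s * lambda` and a flat prior on `lambda`, the posterior of each library's
rate is Gamma(count + 1, size factor). Paired Monte Carlo draws (default
10,000, seeded) give the posterior of `d = log2(lambda_B) -
log2(lambda_A)`; the generalized fold change at confidence `c` (default
0.01) is the c-quantile of `d` if positive, the (1-c)-quantile if negative,
and exactly 0 when the two quantiles straddle zero. High counts shrink the
posterior onto the raw log2 ratio (the tests check convergence at depth
1e5 within 0.05); low counts shrink the value toward 0. The raw log2 fold
change is reported alongside with a display pseudocount of 1 — the
pseudocount never enters the posterior.

Per-species draw seeds are derived from the master seed and the species id,
so results are invariant under row reordering and subsetting. DE calls use
inclusive thresholds, by default >= 2.0 up and <= -0.5 down (the asymmetry
follows the piRNA analysis the defaults mirror); boundary behaviour has to
be fixed somehow and inclusive matches a "threshold of" phrasing.

Bland–Altman summaries plot, per species, the normalized count difference
(B - A) against the mean ((A + B)/2), with limits of agreement at
mean(diff) ± 2 * sample SD(diff) and the center line at 0, where species
identical in both libraries fall. Whether published limits of this kind are
centered at 0 or at mean(diff) is usually unstated; centering the limits at
mean(diff) with the reference line at 0 is the convention adopted here.

# Repeat aggregation

Repeat reference headers carry `accession|chrom|start|end|strand|name`
(a documented stand-in dialect — the upstream databases' true field order
is not recoverable from their descriptions; coordinates are 1-based
inclusive and used for labelling only). Locus counts are joined with the
RepeatMasker name→class/family catalog; names absent from the catalog
resolve to the sentinel "Unknown" and are retained, mirroring the
"Unknown" category of repeat summaries, never dropped. Accumulation sums
locus counts per class (or family, or name) and orientation — an exact
operation tested against per-read tallying — and the antisense/sense ratio
per class is reported as 0 when the antisense total is 0 and absent when
the sense total is 0. The "Unknown" breakdown keys subcategories by repeat
name and keeps those with a two-library total above 10 and a simple
max/min normalized ratio above 2 (a zero minimum counts as infinite) —
deliberately the plain ratio, not the posterior estimator, as such
breakdown filters predate any shrinkage machinery. Display rounding is
half-to-even at 1 decimal for percentages and 2 for ratios; full-precision
values are authoritative everywhere, including the tests.

# The synthetic generator

The generator defines the study conditions under which the pipeline is
validated. `paperlikeTruth()` builds ~200 expressed miRNA species (lengths
21–23 nt, mode 22), a five-member near-identical "let-7-like" family with
true log2 fold changes between 2 and 4 up in library B, ten further
up-regulated and five down-regulated miRNAs, 150 known-but-unexpressed
mature species (so detected-of-known fractions are meaningful), 30
mature-star and 10 hairpin-only species, ~50 expressed piRNAs (24–30 nt)
with strong changes in both directions plus 100 unexpressed ones, and 100
repeat loci in both orientations across L1/L2/MIR/Alu/ERVL families with
L1 loci most abundant, a few L1 sense loci down-regulated, and
scRNA/snoRNA/tRNA-like names that are deliberately missing from the
catalog and up-regulated 2.6–4x. Two spike-in inserts emulate the
introduced silencing and scrambled control constructs (library-specific),
and a few hundred singleton noise reads exercise the singleton filter.

Counts are Poisson per species — with a single library per condition no
replicate dispersion is estimable, so Poisson is the honest noise floor —
with library B means scaled by `2^log2_fc`. Reads are insert + adapter
truncated to 36 cycles, error-free by default so that mapping stays
exact-testable. piRNA lengths are drawn from 24–30 nt: a 31-nt insert
leaves only 5 adapter bases in a 36-cycle read and is unrecoverable under
the 6-base minimum adapter overlap (the emulated library preparation's gel
window also stops at 30 nt). Library sizes land near 10^5 reads — the low
end of the emulated design — which keeps a full two-library run in
seconds; the validation suite runs 100 reduced-size libraries for the
conservation laws (exact arithmetic is scale-free) and 20 full preset
replicates for DE recovery.

What the generator does *not* emulate: sequencing error (available as an
option but off by default), PCR and ligation bias, quality-score realism,
genome-scale reference sizes, multi-locus read provenance, and the
heavy-tailed species abundance of real libraries. Passing tests therefore
show the pipeline's operations are correct and its statistics calibrated
under the stated noise model — not that real-library biases are handled.

# Determinism

Every stochastic step takes a seed: library simulation derives per-library
streams as master seed + library index; the posterior draws derive
per-species seeds from the master seed and the species id. All seeded code
paths restore the caller's RNG state. Identical configuration and seed
produce byte-identical pipeline artifacts, which the tests assert.

# Known limitations

The posterior fold change is a single-library flat-prior construction; it
is not numerically identical to any external implementation of generalized
fold changes, and no p-values or FDR are attached (none are defined
without replicates). The annotation cascade scans references linearly —
appropriate for curated small RNA references (hundreds to tens of
thousands of short sequences), not for genome-scale alignment. Novel-miRNA
prediction, genomic mapping, and conservation analyses are out of scope.
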