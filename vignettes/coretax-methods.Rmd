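---
title: "Methods: read partitioning and homolog-distribution classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read partitioning and homolog-distribution classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coretax)
```

This vignette documents the models, rules and numerical choices behind
`coretax`, in the spirit of a methods section: what each stage assumes,
which parameters matter and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## 1. Read quality control

Raw pyrosequencing reads are preprocessed in a fixed order:

1. **3' trimming.** The trailing run of bases with Phred quality below
   `trim_q` (default 10) is removed; interior low-quality bases are
   untouched. Trimming precedes all filters because length and
   mean-quality criteria are only meaningful on the read that survives
   into downstream analysis — the convention of standard preprocessing
   tools for this platform.
2. **Filters**, each strict as stated: length < 200 bp; mean Phred
   quality < 20; fraction of ambiguous bases (N) > 1% (a read at
   exactly 1% is kept); DUST complexity score > 7.
3. **Artificial-replicate removal.** Reads with identical sequences, or
   that are exact reverse complements of one another (equal length is
   implied), are artifacts of emulsion PCR; every group keeps its first
   member in input order — a deterministic choice, since nothing
   distinguishes the copies.

Every removed read is attributed to the *first* criterion it fails in
this order, so the per-criterion counts plus the kept count always sum
to the input count. This makes audit tables exact and makes the report
insensitive to double violations.

**DUST scaling.** Only the algorithm's name and a threshold of 7 pin
down the complexity filter, so the score is defined here explicitly:
with `m = L − 2` overlapping triplets and counts `c_k`, the raw score
`S = Σ c_k(c_k−1)/2` is normalized to `100·S / (m(m−1)/2)`. The score
is 0 when all triplets are distinct and exactly 100 for a homopolymer
(all triplets identical), with the threshold-7 convention of common
preprocessing tools. Scoring is whole-read rather than windowed: at
typical 454 read lengths (200–600 bp) windowing changes little, and the
whole-read score makes the homopolymer/diversity bounds exact and
testable. Reads with fewer than two triplets carry no repeat signal and
score 0; they are in practice unreachable because the length filter
removes reads under 3 bases first.

**Phred encoding** is offset-33 by default, configurable to offset-64
for legacy data.

## 2. rRNA / mRNA partitioning

Reads are screened against an SSU and an LSU rRNA reference; hits come
in as 12-column tabular homology results. Hits with e-value above
`1e-10` are invisible to all downstream logic — the cutoff is applied
*before* arbitration, so a database in which a read has only weak hits
cannot win merely by a high bit score. A read passing in one database
takes that label; passing in both, it goes to the database whose best
hit has the higher bit score. The best hit itself maximizes bit score
with deterministic tie-breaks (lower e-value, then lexicographically
smallest subject id), which makes classification invariant to row order
in the hit tables.

A tie in best-hit bit score *across* the two databases is resolved to
SSU. Ties are rare in real searches (bit scores are continuous); fixing
the direction keeps the partition deterministic. Small-RNA reads are
subtracted from the non-rRNA fraction as a precomputed id list — the
covariance-model search that produces it is an external tool, and
consuming its output keeps the module's contract format-stable.

## 3. OTU assignment and dominant groups

SSU rRNA reads are mapped closed-reference: each read joins the OTU of
its best hit's reference if the best hit's percent identity meets the
cutoff (default 95%, i.e. 5% divergence), otherwise it is `UNMAPPED`.
The identity of the *best-bit-score* hit is used as reported in the hit
table, not recomputed and not replaced by the best identity among all
hits — mapping is a property of the winning alignment. Unmapped reads
stay in denominators and surface as a `novel` bucket, so abundance
fractions are relative to *all* SSU reads and sum to 1.

Reference dereplication is greedy input-order centroid clustering at
99% global alignment identity (matches / alignment length, computed
with Biostrings pairwise alignment). Greedy input-order clustering is
the standard dereplication idiom; the output guarantees no two
centroids at or above the cutoff.

**Dominant groups.** A taxon is dominant if it persistently exceeds 5%
relative abundance at every timepoint, or if it shows a marked fold
increase from first to last timepoint. The fold threshold is a genuine
free parameter — "significant fold increase" is not a quantity — and
defaults to 2, configurable; the persistence rule does not depend on
it. The rule is applied at the lowest taxonomic rank at which a taxon
clears it, and non-dominant order-level taxa above a 3% cap are
reported so the "no other group above 3% at order level" side condition
can be checked rather than assumed.

## 4. Homolog-distribution classification

The central rule, over a panel of K taxon-specific protein databases
(domain-flagged bacterial/archaeal/eukaryotic), from each read's
presence/absence profile at a bit-score cutoff of 50 (inclusive: a hit
at exactly 50 counts):

- present in all K, **or in all bacterial members** → `CORE`;
- else present in exactly one → `TAXON_SPECIFIC` (that taxon);
- else present in ≥ 2 → `NONCORE_SHARED`;
- else (absent everywhere): `MINOR` with a global-database homolog,
  `NOVEL` without.

The bacterial relaxation is taken literally: it applies whenever every
bacterial-flagged database is present, regardless of archaeal or
eukaryotic presence, because inter-domain sequence divergence can hide
true homologs. Two consequences are worth noting. A read present only
in the single eukaryotic member of a panel is `TAXON_SPECIFIC`, not
core. And if a panel had exactly one bacterial member, presence in it
alone would satisfy the bacterial-core rule — the core branch is
checked first, so such a read is core; panels in practice have several
bacterial members. The rule table is verified exhaustively against an
independent brute-force implementation for every signature × nr-flag ×
domain-composition combination at K = 2…5.

Presence means *any* hit at/above the cutoff in that database, not only
the best hit — the classification is about homolog existence, not about
which homolog is closest. The global-database (nr) homolog flag is
consumed as a precomputed id list; if absent, profiles with no panel
hits conservatively classify as `NOVEL`, with a warning.

Venn tallies count reads per non-empty presence signature; their sum
equals the dominant-group-derived read count by construction. Summary
fractions follow the field's conventions: the dominant-derived share is
relative to *annotated* reads (total minus novel), and core/non-core
shares are relative to dominant-derived reads.

## 5. Community and functional statistics

**Bray-Curtis.** `BC = Σ|x_i − y_i| / Σ(x_i + y_i)` over the union of
taxa, absent taxa counted as 0 — index alignment is the only free
choice here and the union convention keeps the bounds exact: 0 iff the
compositions are identical on the shared index, 1 iff supports are
disjoint.

**Normalized taxon-specific abundance.** A group's share of
taxon-specific reads is rescaled by the dominant-derived fraction:
`(specific_g / Σ specific) × (dominant-derived / annotated)`. The
verbal definition of this normalization admits more than one formula;
this reconstruction satisfies its stated constraint — values sum to the
dominant-derived fraction over groups — and is kept behind a single
function so an alternative can be swapped without touching callers.

**Yates-corrected chi-square.** For a 2×2 table the statistic is
`Σ (max(0, |O−E| − 0.5))² / E` with expectations from the margins and a
p-value from χ²(1). The correction is clamped at zero so proportionally
identical tables score exactly 0 — the modern textbook convention, and
the behavior of `chisq.test(correct = TRUE)`, against which the
implementation is cross-checked. Degenerate tables (a zero margin) are
an error, not a silent 0. Differential-subsystem screening tests each
subsystem against the rest at α = 0.01 on raw p-values by default —
matching the reported-raw-P convention of the original analyses — with
an optional `p.adjust` method for users who want family-wise control.

## 6. The synthetic-data generator

The generator emulates every input the pipeline consumes, with ground
truth, under a single random stream seeded once (module order fixed, so
regenerating with the same seed is byte-identical).

- **Reads.** Clean reads: lengths ~ Normal(420, 80) truncated to
  [250, 600] bp — matching the reported 423–469 bp average read lengths
  of 454 libraries — with per-base qualities ~ Normal(34, 3) under a
  linear 3' decay of 0.01/base, clamped to [21, 40] so clean reads pass
  every default filter by construction. Planted violations are
  *disjoint* (one criterion per bad read) at rates 3% short, 3%
  low-quality, 2% high-N, 2% low-complexity, 3% exact duplicates, 2%
  reverse-complement duplicates, so per-filter counts are checkable
  exactly; an overlap mode additionally plants short+low-quality reads
  to exercise first-failure attribution. A fifth of the clean reads get
  a low-quality 3' tail that the trimmer must remove without changing
  any filter outcome; duplicate sources are never tailed, so replicate
  detection operates on trimmed sequences as in the real pipeline.
- **rRNA mixture** 40/10/50 SSU/LSU/non-rRNA among kept reads, with a
  decoy model (cross-database hits at strictly lower bit score;
  above-cutoff e-values for non-rRNA reads) that must not change any
  label — the arbitration rules are thereby exercised, not bypassed.
- **Community composition and identity strata.** Six taxa at fractions
  0.28/0.12/0.14/0.12/0.09/0.25; best-hit identities fall in [95,100],
  [90,95), [85,90), <85 at rates 0.80/0.15/0.03/0.02, reproducing the
  observed behavior that ~20% of SSU reads fail the 95% cutoff while
  ~98% map by 85%.
- **Partition mixture.** Over mRNA reads: core-all 0.150,
  bacterial-core 0.1175, taxon-specific 0.250, shared 0.1773, minor
  0.2052, novel 0.100. These expectations reproduce the oxic-zone
  headline shares — 77.2% of annotated reads dominant-group-derived,
  38.5% of those core — while exercising every branch of the
  classifier. Shared signatures are drawn uniformly among proper
  subsets of size ≥ 2 that never cover all bacterial members (which
  would be core); such signatures require K ≥ 3, which the
  configuration validates.

What the generator does **not** emulate: real sequence evolution
(reads are i.i.d. uniform nucleotides, so homology is asserted through
hit tables, not alignable sequence), chimeras, platform-specific
homopolymer miscalls beyond the planted low-complexity reads, correlated
noise between databases, and taxonomic structure deeper than a
planted lineage (community taxa sit at phylum rank with synthetic
lower ranks). Passing tests therefore demonstrate that the *decision
logic* is correct under controlled inputs — exact recovery of planted
truth in noise-free settings, stability under decoys — not that any
particular biological dataset would be classified correctly; that
depends on the external searches the pipeline consumes.

## 7. Problem sizes and numerical notes

The shipped tests run the full chain on a seeded 10,000-read scenario
(the scale at which every stage, including replicate detection and
DUST scoring, is exercised in seconds), sweep all 2×2 tables with
margins ≤ 50 against a closed-form oracle, and pool 20 seeds × 10,000
reads for multinomial composition recovery, comparing pooled fractions
within 3 standard errors. Monte-Carlo null calibration of the
Yates-corrected test uses 10,000 tables at n = 5,000 per sample, where
the continuity correction is numerically negligible and the nominal
α = 0.01 is recovered within binomial error.

Floating-point notes: Bray-Curtis at its bounds is exact (0 and 1
arise from exact cancellation and equal sums, not rounding); the Yates
statistic is evaluated cell-wise and agrees with the closed-form
`n(max(0,|ad−bc|−n/2))² / (r₁r₂c₁c₂)` to < 1e-9 across the sweep;
greedy dereplication is order-dependent by design (first occurrence
founds the centroid), which is deterministic for any fixed input
order.

## 8. Known limitations

- The homology searches themselves (BLAST/INFERNAL) are out of scope;
  the package starts from their tabular outputs, so its results are
  conditional on search sensitivity.
- Closed-reference OTU assignment cannot discover taxa absent from the
  reference; unmapped reads are only bucketed as novel.
- The fold-change branch of dominant-group detection compares first
  and last timepoints only; a taxon that spikes mid-course and returns
  is not flagged by it (the persistence branch may still catch it).
- `normalized_specific_abundance` implements one defensible reading of
  an under-specified normalization (Section 5) and is isolated so it
  can be swapped.
- Taxonomic assignment of mRNA reads by top-hit/LCA against a global
  database is consumed as labels where needed, never computed here.
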