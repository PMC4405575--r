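# coretax

Metatranscriptome read partitioning and core / non-core / taxon-specific
transcript classification.

## The problem

A metatranscriptome library from a mixed microbial community — say, the
oxic surface layer or anoxic bulk soil of a flooded rice paddy — mixes
ribosomal and messenger RNA from hundreds of taxa. Two questions drive
the analysis. First, *who is active?* The share of cellularly expressed
SSU rRNA attributable to each taxon is a proxy for its protein synthesis
potential, so SSU rRNA reads are mapped to a dereplicated reference set
and aggregated into taxon abundance tables. Second, *who does what?*
Conventional top-hit annotation of mRNA reads is confounded by database
bias, horizontal transfer and the high conservation of housekeeping
genes. `coretax` instead classifies each putative mRNA read by the
**distribution of its homologs** across taxon-specific protein databases
built for the community's dominant groups:

- **core** — homologs in all K databases, or at least in all
  bacterial-flagged ones (inter-domain sequence divergence can hide true
  homologs): ubiquitous functions shared by the dominant groups;
- **non-core shared** — homologs in two or more, but not all, databases:
  e.g. a methanol dehydrogenase transcript shared exclusively by a
  methanotroph and a methylotroph points to metabolite cross-feeding;
- **taxon-specific** — a homolog in exactly one database: the clearest
  signature of what one group uniquely expresses;
- **minor** — no homolog in any panel database, but one in the global
  protein database (reads from non-dominant groups);
- **novel** — no homolog anywhere.

Formally, a read with presence vector `s ∈ {0,1}^K` over panel databases
with bacterial subset `B` is core iff `∑ s_k = K` or `∑_{k∈B} s_k = |B| > 0`;
otherwise taxon-specific iff `∑ s_k = 1`, non-core shared iff `∑ s_k ≥ 2`,
and minor/novel by the global-database flag iff `∑ s_k = 0`.

The package implements the whole chain around that classification:

1. **preprocess** — 3' quality trimming (Phred < 10), then length
   (< 200 bp), mean-quality (< 20), ambiguity (> 1% N) and DUST
   low-complexity (score > 7 on a 0–100 scale) filters, then
   artificial-replicate removal (exact and reverse-complement
   duplicates), with exact per-criterion accounting;
2. **rRNA partition** — SSU / LSU / non-rRNA assignment from 12-column
   tabular homology hits (e-value ≤ 1e-10) with best-hit bit-score
   arbitration, and small-RNA subtraction to leave putative mRNA reads;
3. **OTU assignment** — closed-reference mapping at a percent-identity
   cutoff (default 95%), mapping-efficiency curves, taxon abundance
   tables with a `novel` bucket, and dominant-group detection
   (persistently > 5%, or marked fold increase, with a 3% order-level
   cap on everything else);
4. **partition** — the homolog-distribution classification above, with
   Venn tallies over presence signatures and summary fractions;
5. **profiling** — Bray-Curtis dissimilarity
   `BC = Σ|x_i − y_i| / Σ(x_i + y_i)` between taxonomic compositions,
   normalized taxon-specific abundance, key-function expression
   profiles, and Yates-corrected chi-square tests for differentially
   represented functional subsystems (two-sided, P < 0.01);
6. **synth** — a fully seeded generator that emulates every input with
   known ground truth (planted QC violations, rRNA classes, community
   composition, identity strata, partition mixtures), so the whole
   chain is testable end to end without external databases.

## Worked example

```r
library(coretax)

scn <- simulate_scenario(synth_config(seed = 42, n_reads = 5000))
qc  <- preprocess_reads(scn$reads)
qc$report
#> qc_report: 5000 reads in, 4250 kept
#>   removed (length): 150
#>   removed (mean_quality): 150
#>   removed (ambiguity): 100
#>   removed (complexity): 100
#>   removed (replicate): 250

rr <- partition_library(qc$kept$id, scn$ssu_table, scn$lsu_table,
                        scn$smallrna_ids)
rr
#> rrna_partition: 4250 reads
#>   SSU rRNA: 1717
#>   LSU rRNA: 407
#>   non-rRNA: 2126 (putative mRNA: 2035)

prof <- build_hit_profiles(scn$panel_hits, universe = scn$mrna_universe,
                           nr_ids = scn$nr_ids)
res <- partition_mrna(prof, scn$config$panel)
res
#> partition_result over 2035 mRNA reads, 5 taxon databases
#>   novel: 207 | minor: 426 | dominant-derived: 1402 (76.7% of annotated)
#>   core: 527 (37.6%) | non-core shared: 379 | taxon-specific: 496

mapping_efficiency(scn$tag_hits, c(95, 90, 85), tag_ids = rr$ssu_ids)
#>    95    90    85
#> 0.816 0.957 0.985
```

Reading the numbers: the QC report accounts for every input read
exactly once (the five removal counts plus the kept count sum to
5000). Of the surviving reads, the rRNA partition is exhaustive and
mutually exclusive; the putative mRNA set is the non-rRNA fraction
minus small-RNA reads. In the partition, 76.7% of annotated mRNA reads
have a homolog in at least one dominant-group database and 37.6% of
those are core — recovering the generator's planted mixture. The
mapping-efficiency curve shows ~82% of SSU reads mappable at the 95%
identity cutoff, rising towards 98% as the cutoff drops to 85%, the
planted identity structure.

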