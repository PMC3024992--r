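# mhctyper

Read-to-genotype analysis of ultra-complex multilocus MHC class IIB
amplicon sequencing data.

Passerine-type MHC class IIB systems carry many similar loci — expressed
genes and pseudogenes — whose alleles cannot be assigned to loci and must
be genotyped simultaneously from one amplicon per individual. The hard part
is telling true alleles from artifacts: PCR substitution errors, in vitro
recombinants (PCR chimeras), homopolymer indel errors, and reads attributed
to the wrong individual through tag errors. `mhctyper` implements a
complete, tested workflow for this problem:

- **Demultiplexing** of `tag + primer + target` reads with IUPAC-degenerate
  primer matching, fixed-length analysis windows, and an empirical upper
  bound on tag misassignment from reads carrying unused tags.
- **Artifact filtering**: the replication ("2-PCRs-3-copies-in-each")
  criterion; homopolymer-indel artifact flagging; and MPAF-sorted PCR
  chimera classification. A variant with maximum per-amplicon frequency
  (MPAF) below the grey-zone bound is labelled a chimera only if, in all
  three amplicons where it is most abundant, it equals a single crossover
  `A[1..k] ++ B[k+1..L]` of two strictly more abundant sequences `A`, `B`
  of the same amplicon. The MPAF threshold above which no chimeras occur is
  derived from the data and scaled to other abundance strata by their mean
  per-amplicon read proportions.
- **Classification** of variants into pseudogene cluster I (diagnostic C/T
  base, 1–2 bp frameshift deletion), pseudogene group II.A (9-bp + 1-bp
  deletions) and putative expressed alleles (intact reading frame), with
  cDNA cross-checking, Tamura–Nei (TN93) distances and neighbor-joining
  trees with bootstrap support.
- **Genotyping**: per-amplicon allele calls, conservative allele counts
  that discard within-amplicon chimera-explainable calls, minimum locus
  numbers under diploidy (`ceiling(max alleles / 2)`), and replicate
  concordance.
- **Selection statistics**: Nei–Gojobori dN/dS with Jukes–Cantor
  correction, antigen-binding-site partitioning, codon-bootstrap standard
  errors and the Z-test of positive selection,
  `Z = (dN − dS) / sqrt(SE_dN² + SE_dS²)`.
- A **ground-truth simulator** that generates tagged reads with multilocus
  diploid genotypes, amplification skew, substitution errors,
  single-crossover chimeras, homopolymer indels and tag corruption, so
  every stage is testable without external data.

## Worked example

```r
library(mhctyper)

# simulate a run at the default study conditions: 40 amplicons,
# mean coverage 500, 5% chimeric reads, substitution rate 1e-3
sim <- simulate_run(sim_config(), seed = 42)

pipe <- mhc_pipeline(sim$reads, sim$sheet, sim$config$primer_iupac,
                     window = 188)

pipe$misassignment$misassignment_rate_upper_bound
#> [1] 0.003661471
table(pipe$report$status)
#> below-threshold putative allele
#>            3613              71
pipe$thresholds$scaled
#>    cluster_I expressed_II    group_IIA
#>  0.031643751  0.007092199  0.004268539

ev <- evaluate_against_truth(sim, pipe$table, pipe$report)
ev$recall
#>   overall expressed  cluster1       iia
#>         1         1         1         1
```

The misassignment bound (~0.33%) is the fraction of reads whose tags match
none of the used tags; `report$status` separates variants that failed the
replication criterion ("below-threshold") from putative alleles, PCR
chimeras and homopolymer sequencing artifacts; `thresholds$scaled` are the
MPAF acceptance thresholds per sequence cluster, obtained by scaling the
derived expressed-allele threshold by each cluster's mean per-amplicon read
proportion; and `recall` is the fraction of detectable true alleles
recovered, per cluster (1.0 across the board here).

Locus arithmetic and threshold scaling are plain calls:

```r
min_locus_count(17)                          # 9 expressed loci
round(100 * scale_threshold(0.0097, 0.164, 0.718), 2)   # 4.25 (%)
```

A thin command-line front end over the same functions is installed at
`inst/cli/mhctyper.R` with subcommands `demux`, `filter`, `classify`,
`genotype`, `selection` and `simulate`.

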