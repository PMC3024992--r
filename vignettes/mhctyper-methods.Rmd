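---
title: "Genotyping complex multilocus MHC amplicon data with mhctyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping complex multilocus MHC amplicon data with mhctyper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

## The problem

Many vertebrates carry the MHC class IIB exon 2 region in many similar
copies: several expressed loci plus pseudogene loci whose alleles cannot be
assigned to individual loci and must be genotyped simultaneously from a
single amplicon. Deep amplicon sequencing makes this feasible, but every
amplicon is a mixture of true alleles and artifacts: PCR substitution
errors, in vitro recombinants (PCR chimeras), platform-typical
insertion/deletion errors in homopolymer runs, and reads attributed to the
wrong individual through tag errors. `mhctyper` implements a complete
read-to-genotype workflow for such data: tag demultiplexing with an
empirical misassignment bound, a replication-based pre-filter, a
chimera-classification procedure driven by the maximum per-amplicon
frequency (MPAF), pseudogene/expressed classification, per-individual allele
calling with conservative locus-number estimation, and supporting selection
statistics (Nei–Gojobori dN/dS with a Z-test) and phylogenetics (Tamura–Nei
distances, neighbor joining). A ground-truth read simulator makes every
stage testable without external data.

## Demultiplexing and the misassignment bound

Reads have the layout `tag + forward primer + target`. The forward primer
(IUPAC degeneracy expanded) is located exactly by default; a mismatch
tolerance is available but off, because with a 23-bp primer an exact scan
already recovers virtually all genuine reads. The tag is read immediately
5' of the primer match, and the retained sequence is the first `window`
bases 3' of it (default 188 bp). Reads whose post-primer segment is shorter
than the window are dropped, keeping all per-amplicon frequencies on a
fixed-length fragment; presence of the reverse primer is deliberately not
required, since requiring it discards a substantial share of otherwise good
reads. Reads are scanned in both orientations by default.

Only a small subset of the possible tags is ever used in a run. A read
whose (complete) tag matches no used tag must carry a tag synthesis or
sequencing error, and because the unused portion of the tag space is close
to 1, nearly all corrupted tags land outside the used set. The observed
unused-tag read fraction therefore bounds the rate at which corrupted tags
silently land *on* used tags and misassign reads. `estimate_misassignment()`
reports the unused fraction of the tag space, the rate bound, and the
expected number of misassigned reads per amplicon at the observed coverage.
Tags one substitution away from a used tag are never rescued: with used
tags kept at pairwise distance of at least three substitutions, a one-off
tag is overwhelmingly an error and the conservative choice is to leave it
unassigned.

## The artifact filter

The filter operates on the variant table (unique window sequences by
amplicons, with per-amplicon read totals as frequency denominators).

**Replication criterion.** A variant is a candidate if it occurs in at
least `min_pcrs = 2` amplicons with at least `min_copies = 3` reads in
each. Two independent PCRs is the standard replication requirement;
three copies per PCR reflects the probabilistic argument that the same
substitution artifact is very unlikely to recur three times. Every
amplicon, including replicates of one individual, counts as an independent
PCR.

**Homopolymer artifacts.** Among candidates, a variant differing from a
more abundant candidate by exactly one 1-bp indel inside a homopolymer run
of length ≥ 3 — and by nothing else — is flagged as a sequencing artifact.
Because the analysis window is cut from longer reads at fixed length, a
template indel shifts one flanking base into (deletion) or out of
(insertion) the window; the detector handles both the plain different-length
case and this shifted fixed-window case.

**Chimera classification.** A PCR chimera must co-occur with both parental
sequences in its amplicon, each necessarily more abundant than the chimera
itself. Candidates are sorted by ascending MPAF and each variant below the
grey-zone bound (`grey_zone_upper = 0.015`) is examined in the three
amplicons where it is most abundant (raw read count, ties broken by
amplicon frequency and then amplicon identifier for determinism; if the
variant occupies fewer than three amplicons, all of them). The variant is
labelled a PCR chimera only if, in *all* examined amplicons, it can be
written as a single-crossover of two sequences with strictly more reads
there. Every chimera label carries a witness (parent pair and breakpoint)
that reconstructs the variant exactly. Parents may be any observed sequence
in the amplicon, not only candidates — the more conservative choice toward
chimera calls; a flag restricts parents to candidates. Ties in abundance do
not qualify as parents, which prevents two equal-count variants from
explaining each other away. Classification is a single pass: labelling a
variant as a chimera does not remove it from the parent pool, because no
re-evaluation rule is defined for the procedure and a single deterministic
pass is reproducible. Double-crossover search is not performed: the single
crossover model already explains the dominant chimera mechanism, and the
quadratic cost of the double-crossover scan buys mostly false flexibility
(almost any variant becomes "explainable" given two crossovers between
similar parents).

**Threshold derivation and scaling.** After classification,
`derive_threshold()` returns the smallest putative-allele MPAF above the
largest chimera MPAF: above this value no variant was classified as a
chimera, so variants there can be accepted without individual examination.
In low-divergence strata (pseudogene clusters) chimeras are
indistinguishable from alleles over a wide MPAF range and no clean
threshold exists; there the expressed-allele threshold is scaled by the
ratio of mean per-amplicon read proportions
(`scale_threshold(base, p_base, p_target)`), assuming the PCR recombination
rate is similar across strata.

**Known failure mode.** A true recombinant allele that happens to co-occur
with both of its (more abundant) evolutionary parents in all examined
amplicons is indistinguishable from a PCR chimera and will be discarded.
This is the price of the co-occurrence rationale and is covered by a
dedicated test; the procedure is deliberately conservative in this
direction.

## Cluster assignment and expression status

Variants fall into three sequence groups with distinct signatures: a
low-divergence pseudogene cluster marked by a C/T diagnostic base directly
behind the forward primer and a 1–2 bp frameshift deletion; a second
pseudogene group (within the expressed cluster's diagnostic-G side) marked
by characteristic 9-bp plus 1-bp deletions; and the divergent expressed
cluster with intact reading frames. `assess_coding()` aligns each variant
globally to a functional reference, extracts indel events, and declares a
frameshift as soon as the cumulative net indel length over any alignment
prefix is not a multiple of 3; translation is scanned for internal stops
only up to the point of frame loss. The default reference is the
majority-rule consensus of stop-free variants from the diagnostic-G side —
a data-driven surrogate for a known expressed allele, chosen because the
low-divergence pseudogene cluster would otherwise dominate the consensus
column votes; a user-supplied reference overrides it. The codon phase of
window position 1 defaults to 0 and is configurable. Deletion signatures
are detected by alignment, not hard-coded coordinates, since the exact
deletion positions vary with primer placement.

cDNA cross-checking (`match_cdna()`) uses exact string matching of cDNA
variants supported by at least two clones, mirroring how expression is
typically confirmed.

Tamura–Nei (TN93) distances are computed with pairwise deletion of gapped
sites by default (complete deletion by flag), and saturated pairs are
reported as `Inf` rather than silently dropped. Neighbor joining follows
the canonical Q-matrix agglomeration; bootstrap support resamples alignment
columns with a seeded RNG (default 1000 replicates when requested).

## Genotyping and locus numbers

`call_alleles()` lists accepted alleles with at least `min_reads = 2` reads
in an amplicon. `conservative_count()` then discards every called allele
explainable as a single crossover of two more abundant called alleles of
the same amplicon — some of these are true recombinants, so the resulting
count is a lower bound by construction. Under diploidy the minimum locus
number is `ceiling(max_alleles / 2)`. Replicate concordance follows the
printed evidentiary rule: an allele is *shared* with at least one read in
every replicate of an individual, and *single-replicate* with at least two
reads in exactly one replicate and zero in all others (the two-read
requirement avoids counting stray misassigned reads as discordance); with
three replicates, "shared" requires presence in all three.

## Selection statistics

`ng_site_counts()` and `pairwise_ng()` implement the Nei–Gojobori method:
per-codon synonymous/nonsynonymous site counts with stop-codon targets
excluded from the per-position denominator, observed differences
partitioned by equal-weight averaging over all minimal mutational pathways
(pathways through stop codons excluded; if every pathway is blocked, all
pathways are used with steps into stops counted as nonsynonymous), and the
Jukes–Cantor correction with an explicit saturation flag at p ≥ 3/4.
Gap- or stop-containing codon pairs are excluded pairwise.

`mean_rates()` averages pairwise dN and dS over all sequence pairs within a
codon partition (all sites, antigen-binding sites, or their complement) and
obtains standard errors by bootstrap over codon columns within the
partition (default 1000 seeded replicates); the bootstrap is the SE of
choice because the analytical variance is unreliable for partitioned,
pairwise-averaged rates. The Z-test uses
Z = (dN − dS) / sqrt(SE_dN² + SE_dS²) against the standard normal; the
one-tailed "positive selection" alternative is the default and a two-sided
version is exposed, since presentations of this test differ. The
antigen-binding-site codon list ships as an editable configuration file
(derived from the human class II contact residues) rather than hard-coded
positions, because the mapping onto any particular amplicon depends on
primer placement and the structural reference.

## The read simulator

`simulate_run()` emulates the study conditions end to end, and its defaults
are fixed at those conditions rather than tuned per test: 188-bp windows
behind a 6-bp tag (used tags kept ≥ 3 substitutions apart) and a 23-bp
degenerate forward primer; 20 individuals each amplified twice (40
amplicons); per-amplicon coverage drawn normal with mean 500 and SD 150;
cluster read proportions 0.164 / 0.718 / 0.118 for expressed / cluster I /
group II.A; 9 expressed, 10 cluster I and 5 group II.A diploid loci drawn
from pools of 30 / 30 / 12 alleles; expressed-pool mean pairwise divergence
0.10 with intact reading frames; cluster I alleles within pairwise Hamming
distance 2 of each other plus the shared 1–2 bp deletion; group II.A with
the shared 9-bp + 1-bp deletions; log-normal per-allele amplification skew
(σ = 0.5); i.i.d. substitution errors at 10⁻³ per base; 5% of reads formed
as single-crossover chimeras with uniform breakpoints (chimeric reads never
seed further chimeras); homopolymer indels at probability
rate × (run length − 2) per run of length ≥ 3 (rate 10⁻³, the simplest
monotone length scaling); and i.i.d. per-base tag corruption at 5.5 × 10⁻⁴,
which yields roughly 0.33% of reads with corrupted tags. All three cluster
ancestors descend from one master template (≈ 12% substitution divergence)
so that cross-cluster alignments remain meaningful, as they are for a real
multigene family. Template regions carry 30 bp of buffer behind the window
so that deletions shift flanking sequence into the fixed window exactly as
fixed-length read trimming does.

What the simulator does *not* emulate: flowgram-level signal, quality
scores, indel errors outside homopolymer runs, chimeras of chimeras, PCR
drift in cluster proportions between amplicons, and contamination.
Passing tests on simulated data therefore demonstrate the correctness of
the bookkeeping and the discriminating logic under the stated error model,
not robustness to every artifact of a real sequencing run.

`evaluate_against_truth()` scores pipeline output with a
detectability-aware recall: only true alleles whose window sequence meets
the replication criterion in the observed table enter the denominator,
because no frequency-based filter can recover an allele the reads do not
support. Chimera metrics distinguish overall sensitivity from the
guaranteed subset (a true parent pair strictly more abundant in every
examined amplicon and MPAF inside the scanned zone), which the procedure
must flag without exception.

## Numerical and design notes

- MPAF denominators are the full per-amplicon read totals (including
  singleton reads), not the post-filter totals.
- Processing order and all tie-breaks (MPAF sort, amplicon selection,
  descending-abundance pass in conservative counting) are deterministic;
  identical inputs give identical outputs.
- `scale_threshold` is exact linear arithmetic; tests hold it to 1e-12.
- Sequences are compared ungapped at fixed window length throughout the
  filter; length-variant alleles enter via the windowing mechanism rather
  than explicit alignment.
- The spot-check utility for variants above the grey zone draws a seeded
  random sample; the sampling scheme used on any historical dataset is not
  reproduced, only the operation.
- Saturated TN93 pairs (`Inf`) make a distance matrix unusable for NJ by
  design; the caller must prune or recode, rather than the package
  silently imputing.
- Problem sizes in the test-suite property checks (for example 1000 random
  amplicons for the chimera oracle, 50 random trees for NJ consistency,
  1000 neutral alignments of 8 sequences × 50 codons for the Z-test
  calibration, and one 40-amplicon simulated run at coverage 500 for the
  end-to-end check) were chosen as the smallest sizes at which the
  binomial/normal approximations underlying each check are comfortable.

## Limitations

- Locus assignment of alleles, haplotype phasing and population allele
  frequencies are out of scope.
- The conservative allele count is a lower bound; with highly similar
  pseudogene alleles it can be far below the truth.
- The misassignment bound is an upper bound on average; it does not model
  tag-specific error rates.
- PAML-style codon models, recombination detection and Bayesian
  phylogenetics are intentionally not provided.
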