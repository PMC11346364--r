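---
title: "Methods: diversity-peak scans, genetic load, and ROH in low-diversity genomes"
author: "lowdivscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity-peak scans, genetic load, and ROH in low-diversity genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Some endangered species persist for millennia with tiny effective population
sizes and genome-wide heterozygosity an order of magnitude below that of
their widespread relatives. Two signatures are diagnostic when reading such
a genome. First, *localized diversity peaks*: windows whose nucleotide
diversity stands far above the genomic background, often spanning immune,
sensory or synaptic gene clusters, and — when maintained by balancing
selection — showing *reduced* differentiation against a related species.
Second, *genome-wide erosion*: elevated nonsynonymous-to-synonymous
heterozygosity (genetic load) and long runs of homozygosity (ROH) from
inbreeding. `lowdivscan` implements the full windowed scan that extracts
both signatures from a reference genome (FASTA), gene models (GFF3), joint
diploid genotypes for a focal and a contrast species (VCF), and per-window
mappability/coverage tracks, together with a seeded synthetic-genome
generator so that every stage is testable without external data.

## Statistics and models

### Windowed nucleotide diversity and peaks

Per segregating site with `n` non-missing haplotypes and allele frequencies
`p_a`, diversity is the unbiased mean pairwise difference

    pi_site = (n / (n - 1)) * (1 - sum_a p_a^2),

summed over the SNVs of each non-overlapping 10-kb window and divided by
the **full window span** — not by the number of callable sites. This is the
convention of the common `window-pi` implementations, and the peak
thresholds are defined under it; changing the denominator would shift every
threshold. Monomorphic sites contribute zero; sites with fewer than two
haplotypes are skipped. Terminal windows keep their true (shorter) span and
are flagged rather than dropped.

Windows are filtered before any peak statistics: mean mappability `< 0.8`,
or mean coverage `< 40x` or `> 400x`, marks a window as a likely artifact
(unannotated repeats, collapsed duplications). All three thresholds are
strict inequalities — boundary values pass — and a window without track
data fails conservatively. A passing window is a *peak* when its diversity
strictly exceeds `mean + 4 SD`; mean and SD are computed over **passing
windows only**, because failed windows carry unreliable diversity (the
alternative, pre-filter moments, is not well defined once artifact windows
are admitted; we treat this as the package's convention and expose `k`).
Adjacent peak windows merge into peak regions. Genes overlapping a peak
region whose CDS SNV proportion (CDS SNV count / CDS length) exceeds 0.01
are reported as *polymorphic genes*.

### Between-species differentiation

Per bi-allelic site, the two-population Weir–Cockerham (1984) variance
components `a` (among populations), `b` (among individuals) and `c`
(within individuals, the heterozygote term) are computed from diploid
genotype counts; the window estimate is the weighted ratio
`F_ST = sum(a) / sum(a + b + c)` over usable sites (sites polymorphic in
the pooled sample). Negative components and negative window estimates are
reported as computed — clipping at zero would bias the contrast between
peak and background windows. The peak-vs-background shift is tested with a
two-tailed Mann–Whitney test: exact when both groups have at most 12
windows (a tie-aware enumeration of the rank-sum distribution via dynamic
programming over doubled midranks — the base-R exact path refuses ties),
otherwise the normal approximation with tie and continuity corrections.

### Genetic load

A CDS position is f-fold degenerate when exactly f of the four bases at
that codon position encode the same amino acid (f = 1 is the conventional
"0-fold" class). The load readout is the per-site-normalised ratio

    (het0 / n0) / (het4 / n4),

heterozygous calls at 0-fold sites over 0-fold site count, relative to the
same at 4-fold sites. The raw count ratio `het0 / het4` is also reported,
but the normalised form is the quantity that is comparable across genomes
with different codon composition, and it is what the ratio's interpretation
(efficacy of purifying selection) requires. Positions in overlapping CDS of
two genes are excluded from the ratio; genes with internal stop codons are
excluded and reported. SNV impact classes follow the SnpEff convention:
High = stop gained, start lost, stop lost, or the two intronic bases
flanking a CDS junction; Moderate = missense; Low = synonymous or stop
retained; Modifier = everything else. Stop-lost is not named in the usual
class listings; we place it in High, in line with common impact tables.
Spectra are tabulated over heterozygous SNVs only and normalised over
High/Moderate/Low.

### Runs of homozygosity

ROH are decoded with a two-state HMM over the zygosity sequence of the
sites informative for the sample's species. The outbred state (HW) emits
heterozygotes with probability `2 f (1 - f)` at a constant default allele
frequency `f = 0.4` (so P(het) = 0.48); the autozygous state (AZ) emits
them only through genotyping error (`1e-3`). Per-bp transition rates
(`6.7e-8` into AZ, `5e-9` out — the documented defaults of the standard
ROH caller) are scaled by inter-site distance `d` as `1 - (1 - rate)^d`.
Decoding is Viterbi rather than posterior: it yields deterministic,
reproducible intervals. The start distribution is uniform over the two
states; with fewer than two sites nothing is decoded. Maximal AZ runs
become intervals `[first site - 1, last site)` (the last-site convention,
not extended into the flanking gap), intervals shorter than 100 kb are
discarded, and `F_ROH` is the summed interval length over the total genome
length, reported at full precision and at 2 decimals.

One artifact of distance-scaled transitions deserves a correction: the
cost of leaving the AZ state is roughly `log(rate * d)`, so Viterbi
prefers to place the state switch across a *large* inter-site gap, and
will strand a handful of flanking homozygous sites outside the run when a
cheap gap sits a few sites away. Flanking homozygotes are statistically
indistinguishable from run members, so `call_roh()` refines every decoded
run to the maximal homozygous run containing it (the envelope a
PLINK-style hom-run definition would assign) before length filtering;
`refine_boundaries = FALSE` restores the raw decoded runs.

### Shared diversity peaks between species

Whether `observed` peak windows shared between the two species exceed
chance is tested by Monte Carlo: under the null the `kA` and `kB` peak
labels fall uniformly without replacement on the `N` windows,
independently per species. Because the null is invariant under window
relabelling, each replicate fixes set A and samples set B — half the
sampling for an identical null. Two tails are reported: the strict
`> observed` count (the convention of the printed p-values) with an
add-one correction `(count + 1) / (n_reps + 1)` so that p is never zero,
and the conventional `>= observed` tail. Exact hypergeometric tails at the
same cuts serve as the built-in oracle; the Monte Carlo estimate must sit
within three binomial standard errors of them. `N` defaults to the number
of passing windows when run inside the pipeline, and is an explicit input
otherwise.

## The synthetic-data generator

`sim_config()` fixes the study conditions; its defaults are the conditions
the scan is designed for, not tuning knobs:

* focal species "A": 2 diploid individuals, expected heterozygosity
  `3.4e-4`/bp; contrast species "B": 4 diploids at `16.0e-4`/bp (about
  5x higher), mirroring the two-against-four sample layout of a focal
  endangered genome contrasted with a widespread relative;
* fixed inter-species differences at `5e-3`/bp outside balanced peaks;
* non-overlapping 10-kb windows; per-window mappability near 1.0 and
  coverage from Normal(60, 6), with declared artifact windows forced to
  mappability 0.5 or coverage 20x/600x;
* GC fraction 0.41, a typical teleost value.

Sites are simulated independently (no linkage): every statistic in scope
depends only on marginal per-site frequencies, so linkage would add cost
without adding coverage of the tested behaviour. Minor-allele counts
follow a neutral-like `1/i` distribution truncated to the sample;
declared peaks place sites at intermediate frequency (0.5) at
`pi_multiplier` times the background rate, so realized window diversity
has expectation `pi_multiplier * theta`. Balanced peaks carry the same
polymorphism in both species and exclude fixed differences, which is what
depresses window `F_ST` there. The per-site rate is calibrated so each
individual's expected per-bp heterozygosity equals `theta` exactly (for a
polymorphic site, expected individual heterozygosity equals expected site
diversity under random placement; the generator divides `theta` by that
expectation). ROH tracts force the carrier homozygous; sites left
monomorphic are dropped, as they would never enter a VCF. An optional
load layer plants heterozygotes directly at 0-fold/4-fold sites at
configured per-site rates. Genes are two-exon ORFs (ATG ... stop, no
internal stops, GT..AG introns) planted without overlap, seeding declared
peak intervals first.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: linkage disequilibrium and haplotype
structure, mutation-rate heterogeneity, genotyping error outside the ROH
emission model, reference bias, indels and multi-allelic sites, overlapping
genes, and realistic coverage autocorrelation. The recovery experiments
validate the estimators under the model's own assumptions, not the
upstream variant calling.

## Numerical and design choices

* Coordinates: interval objects (windows, peak regions, ROH intervals,
  BED/BedGraph) are 0-based half-open; variant sites and CDS segments are
  1-based inclusive as in VCF/GFF3. One convention per kind of object,
  standard dialects at the boundaries.
* Genotypes are unphased; only zygosity is used. Sites with missing calls
  are retained and handled per statistic (per-site `n` for diversity,
  per-population `n_i` for F_ST, non-missing sites for ROH).
* The exact Mann–Whitney path enumerates the rank-sum distribution with
  doubled midranks, so ties are exact too; the two-sided p doubles the
  smaller tail and is capped at 1.
* ROH interval recovery is judged at the identifiability limit of the
  data: a flanking homozygous site is indistinguishable from a tract site,
  so any decoder absorbs the maximal adjacent homozygous run. Recovery
  tests therefore require each called boundary to lie between the last
  heterozygous site outside the tract and the first informative site
  inside it (at most one informative-site gap), rather than within a fixed
  distance in bp.
* All randomness flows from one root seed; each stage derives a bounded
  sub-seed, so stage-level outputs are reproducible in isolation and
  byte-identical across runs.
* The pipeline functions themselves are the interface (`run_pipeline()`
  plus the per-stage functions); intermediates are persisted as plain-text
  BED/TSV/VCF when an output directory is given, and the report object is
  re-derivable from them.

## Problem sizes used by the test suite

The packaged experiments run at desk scale, chosen so that each criterion
is measured with adequate statistical margin: heterozygosity calibration
on a 10-Mb single-contig genome (expected ~3,400 heterozygous calls,
relative SE ~1.7%, tested at ±5%); peak recovery and the F_ST shift on
100 seeded genomes of 2 x 1 Mb with five injected 20x balanced peaks;
ROH recovery on 100 seeded 5-Mb genomes with injected 150-kb, 500-kb and
1-Mb tracts; the shared-peak test at the full published scale
(N = 77,860 windows, 10^6 replicates), which is cheap because each
replicate is O(kB).

## Known limitations

* The W&C estimator is implemented for exactly two populations, matching
  the scan's design; multi-population contrasts are out of scope.
* The ROH HMM consumes hard genotype calls (GT), not genotype likelihoods;
  with noisy calls the error rate `epsilon` is the only safety valve.
* Window F_ST applies the same mappability/coverage filters as the
  diversity windows; if the upstream tracks are wrong, both statistics
  inherit the error in the same direction.
* The polymorphic-gene proportion counts SNV sites in CDS against CDS
  length without weighting by zygosity or impact; it is a screening
  statistic, not a substitute for per-gene diversity.
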