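# lowdivscan

Genome-scan diagnostics for endangered, low-diversity diploid genomes.

Some threatened species persist for millennia with tiny effective
population sizes and genome-wide heterozygosity an order of magnitude below
that of widespread relatives. Reading such a genome raises two questions a
conservation genomicist wants answered from one pipeline:

* **Where is diversity retained?** Windows of nucleotide diversity (π) far
  above the genomic background — typically immune, sensory and synaptic
  gene clusters — and, when maintained by balancing selection, showing
  *reduced* differentiation (F<sub>ST</sub>) against a related species and
  peaks *shared* with that species beyond chance.
* **How much erosion has accumulated?** Elevated 0-fold/4-fold degenerate
  heterozygosity (genetic load), a shifted coding-effect spectrum, and runs
  of homozygosity (ROH) summarized as F<sub>ROH</sub>.

`lowdivscan` implements the whole scan on standard inputs (FASTA reference,
GFF3 gene models, joint VCF genotypes for a focal and a contrast species,
per-window mappability/coverage tracks) plus a seeded synthetic-genome
generator so every stage is testable without external data.

## The statistics at the core

* Per-site diversity `π = (n/(n−1))(1 − Σ p_a²)` summed over SNVs of
  non-overlapping 10-kb windows and divided by the full window span;
  windows with mappability < 0.8 or coverage outside [40×, 400×] excluded;
  peaks are passing windows with `π > mean + 4·SD` (moments over passing
  windows), merged when adjacent. Genes in peak regions with CDS SNV
  proportion > 0.01 are reported as polymorphic genes.
* Weir–Cockerham (1984) two-population variance components per site, window
  `F_ST = Σa / Σ(a+b+c)`, and a two-tailed Mann–Whitney test of the
  peak-vs-background F<sub>ST</sub> shift (exact, tie-aware enumeration
  when both groups ≤ 12 windows).
* Fold-degeneracy classification of CDS positions (0/2/3/4-fold), the
  per-site-normalised 0-fold/4-fold heterozygosity ratio, and SnpEff-style
  High/Moderate/Low/Modifier SNV impact classes.
* A two-state HMM (Hardy–Weinberg vs autozygous, default allele frequency
  0.4, genotyping-error emission 10⁻³, per-bp transition rates scaled by
  inter-site distance) decoded by Viterbi; ROH ≥ 100 kb;
  `F_ROH = Σ ROH length / genome length`.
* A Monte Carlo test for the number of diversity-peak windows shared
  between the two species (uniform placement of both peak sets, 10⁶
  replicates by default), cross-checked against the exact hypergeometric
  tail.

## Worked example

Simulate a 2-Mb two-contig genome with one balanced diversity peak (20×
background π, shared with the contrast species), one 300-kb ROH tract and
one low-mappability artifact window, then run the full scan:

```r
library(lowdivscan)

cfg <- sim_config(
  seed = 42,
  peaks = data.frame(contig = "ctg1", start = 2e5, length = 1e4,
                     pi_multiplier = 20, shared_with_b = TRUE, balanced = TRUE),
  roh_tracts = data.frame(sample = "A1", contig = "ctg2",
                          start = 3e5, length = 3e5),
  artifact_windows = data.frame(contig = "ctg1", window = 50L,
                                type = "low_map"))
report <- run_pipeline(cfg, mc_reps = 1e5)
print(report)
```

```
Low-diversity genome scan report (package version 0.1.0 )

Per-sample heterozygosity (/bp):
      A1       A2       B1       B2       B3       B4 
0.000314 0.000386 0.001600 0.001620 0.001660 0.001610 

Windows: 200 total, 199 pass; peaks: 1 window(s) in 1 region(s), threshold 0.00242
Polymorphic genes: 0 of 1 peak-region gene(s)
ROH calls for A1: 1 interval(s) >= 1e+05 bp, F_ROH = 0.1492 (0.15)
ROH calls for A2: 0 interval(s) >= 1e+05 bp, F_ROH = 0.0000 (0.00)
F_ST shift test (two-tailed Mann-Whitney, normal approximation):
  median peak -0.182 (n=1) vs background 0.809 (n=198), U = 0.0, p = 0.0864
Shared peak-window test: observed 1 of min(1, 1) over N = 199 windows
  expected 0.005; p (MC, > observed, add-one) = 1e-05; p (MC, >=) = 0.00512
  exact hypergeometric tails: > 0, >= 0.00503  [1e+05 replicates, seed 3000051]
```

Reading the report: the two focal-species individuals sit at ~3×10⁻⁴
heterozygous sites/bp against ~16×10⁻⁴ for the contrast species (the
configured 5× contrast); the artifact window was filtered (199 of 200
pass); the injected peak window is the single window above the
`mean + 4 SD` threshold; its F<sub>ST</sub> (−0.18, shared polymorphism)
sits far below the background median of 0.81 driven by fixed differences;
the ROH tract is recovered only in its carrier (F_ROH 0.15 ≈ 300 kb / 2
Mb); and a single shared peak among 199 windows is itself already unlikely
by chance (expected 0.005, hypergeometric tail 0.005). Per-stage functions
(`window_pi()`, `filter_windows()`, `detect_peaks()`, `window_fst()`,
`classify_degeneracy()`, `load_ratio()`, `call_roh()`,
`mc_overlap_pvalue()`, …) expose every intermediate; `plot(report)` draws
the π track with the threshold line, the peak-vs-background F<sub>ST</sub>
contrast and the ROH length histogram.

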