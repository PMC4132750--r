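# periodscan

Spectral analysis of ~11 bp dinucleotide periodicity in bacterial genomes.

Many bacterial chromosomes carry AT-tracts — runs of A/T without the TpA
step, each bending the DNA axis — phased at a spacing near the helical
pitch, so the bends accumulate into intrinsic curvature. `periodscan` is an
R package for detecting, quantifying and dissecting this sequence signal:

* **Genome-wide strength and period.** For a dinucleotide motif set
  (default AT2 = {AA, AT, TT}), the binary occurrence track is summarized
  by its autocorrelation function
  `C(k) = (1/((M−k) p̂²)) Σ xᵢ xᵢ₊ₖ` (1 = no correlation), smoothed by
  3 bp to cancel the codon-frame signal, and transformed into a normalized
  power spectrum `Q*(T)` over lags 30–101 bp on a continuous period grid
  2–15 bp. `Q*_SNR`, the maximum of `Q*` in the 10–12 bp band, is the
  genome-wide periodicity statistic; the argmax is the genome's
  characteristic period.
* **Localization.** 200 bp windows, dinucleotide-preserving (Euler/
  uShuffle-style) permutation nulls, per-period p-values
  `P(T,i)` from a shared ensemble, spectrum averaging over four
  consecutive windows, and concatenation of adjacent significant windows
  into periodic genome segments stratified by period range.
* **Annotation statistics.** Jaccard interval-permutation tests of
  segments against CDS/intergenic intervals; cumulative hypergeometric
  enrichment of gene clusters; Ward/complete-linkage profile clustering.
* **Codon dissection.** `Q'`, the fraction of concatenated-CDS band power
  at a probe period surviving codon-order shuffling, synonymous codon
  replacement, or per-position permutation — locating the signal within
  the codon (position III > I > II).
* **Synthetic benchmarks.** A generator for genomes with implanted phased
  AT-tract arrays and for coding sequences whose periodicity is written
  into chosen codon positions, with ground truth for end-to-end
  validation.

## Worked example

```r
library(periodscan)

## a 100 kb genome with phased AT-tract arrays implanted at period 11 bp
spec <- synthetic_spec(seed = 1)
g    <- generate_genome(spec)

fit <- periodicity(g$genome)      # motif AT2 by default
fit
#> Motif periodicity spectrum (motif AT2)
#>   track: 99999 positions, density p_hat = 0.2935
#>   lags 30-101 bp, periods 2.0-15.0 bp
#>   peak period: 11.1 bp   Q*_SNR(10-12 bp): 5.39
```

The fitted peak period (11.1 bp) recovers the implanted 11 bp phasing to
within the 0.1 bp grid, and the band SNR of 5.4 — `Q*` has unit mean, so
values far above 1 mean band-concentrated power — is well above what
background composition produces (about 2–2.5 on iid sequence).

```r
## where in the codon does a coding signal live?
cset <- generate_cds_set(synthetic_spec(seed = 1, n_genes = 40))
q_prime(cset$cds, T_probe = 11.0, n_reps = 10, seed = 2)
#> Codon-permutation attenuation at T = 11.0 bp (10 reps)
#>   P(T) before permutation: 0.001041
#>   codon_order   Q' = 0.003  [0.000, 0.008]
#>   synonymous    Q' = 0.020  [0.008, 0.040]
#>   position_I    Q' = 0.160  [0.120, 0.207]
#>   position_II   Q' = 0.281  [0.222, 0.380]
#>   position_III  Q' = 0.026  [0.012, 0.039]
```

Shuffling the codon order removes essentially all band power (Q' ≈ 0):
the signal is a property of codon arrangement, not composition. It
survives position-II permutation best and position-III permutation worst —
the periodicity is written chiefly into the synonymous third position,
with a weaker share at position I.

```r
## localize the signal along the genome
sc <- scan_genome(g$genome, n_perm = 500, seed = 3)
sc
#> Windowed periodicity scan of synthetic (100000 bp)
#>   125 units of 800 bp (avg4), 500 permutations each (motif AT2)
#>   102 significant windows (P < 0.01), 69 segments
```

With implants covering 40% of the whole genome, most 800 bp units are
significant; `sc$segments` holds the resulting periodic segments per
period range, ready for `jaccard_permutation_test()` against annotation.
Real genomes enter through `read_fasta()` and `read_annotation()` (GFF3 or
GenBank), and `run_full_pipeline()` chains all stages with a manifest.

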