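---
title: "Quantifying ~11 bp dinucleotide periodicity in bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ~11 bp dinucleotide periodicity in bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periodscan)
```

## The signal and why it matters

Runs of A and T that avoid the TpA step — *AT-tracts* — bend the DNA axis
into the minor groove. When such tracts recur at a spacing near the double
helix pitch (~10.5 bp relaxed, longer under negative supercoiling), the
individual bends add up on the same helical face and the molecule acquires
macroscopic intrinsic curvature. Many bacterial chromosomes carry this
phasing as a genome-wide sequence signal with a characteristic period close
to 11 bp, embedded to a large extent inside protein-coding sequence.

`periodscan` quantifies that signal. It measures the strength and period of
dinucleotide motif phasing genome-wide, localizes it along the chromosome
with a composition-controlled permutation test, relates the resulting
periodic segments to annotation, and dissects how the signal is carried by
the three codon positions of coding sequence.

## Core statistics

**Indicator track.** For a motif set $M$ of dinucleotides (the default is
AT2 $= \{AA, AT, TT\}$, the minimal AT-tract unit: all A/T dinucleotides
without TpA), a sequence of length $L$ becomes the binary track
$x_i = \mathbf 1[s_{i..i+1} \in M]$, $i = 1..L-1$. Any dinucleotide
touching an N is a non-match; the motif density is
$\hat p = \sum_i x_i / (L-1)$.

**Autocorrelation.** The lag-$k$ autocorrelation, normalized so that 1
means "no correlation beyond composition":

$$C(k) \;=\; \frac{1}{(M-k)\,\hat p^{\,2}} \sum_{i=1}^{M-k} x_i\,x_{i+k},
 \qquad M = L - 1 .$$

$C$ is then smoothed with a 3 bp centered moving average (truncated at the
edges). The 3 bp window deliberately cancels the strong codon-frame
oscillation of coding DNA, which would otherwise dominate every spectrum.

**Period spectrum.** With $m$ the mean of the smoothed ACF
$\bar C(k)$ over the lag window $k \in [k_{\min}, k_{\max}]$
(defaults 30 and 101 bp) and $n_k$ the number of lags,

$$P(T) \;=\; \frac{1}{n_k}\,\Bigl|\sum_k \bigl(\bar C(k) - m\bigr)\,
  e^{2\pi i k/T}\Bigr|^2 , \qquad
  Q^*(T) \;=\; \frac{P(T)\,\lvert\mathrm{grid}\rvert}{\sum_{T'} P(T')}.$$

The lower cutoff $k_{\min} = 30$ bp excludes short-range correlations such
as those induced by amphipathic alpha-helices in the encoded proteins. The
spectrum is evaluated on a continuous period grid (2–15 bp in 0.1 bp
steps), not on DFT bins, because genome peaks fall at non-bin periods
(11.4, 11.8, 9.8 bp and so on). $Q^*$ has unit mean over the grid by
construction; `band_snr()` reports $Q^*_{SNR}$, the maximum of $Q^*$ in the
10–12 bp helical band, as the genome-wide periodicity-strength statistic,
and `peak_period()` the argmax (ties resolved toward the smaller period).
If the total power falls below $10^{-12}$ the spectrum is degenerate:
$Q^* \equiv 0$, no peak, excluded from all testing.

`periodicity()` wraps track, ACF and spectrum into one classed object with
`print`, `summary`, `plot` and `coef` methods; this is the package's
central estimator, and all other stages are built on it.

## Localizing the signal: the windowed scan

`scan_genome()` tiles the chromosome into 200 bp windows (trailing
remainder discarded) and asks, window by window, whether the observed
spectrum could have arisen from the window's own dinucleotide composition.
The null is the *dinucleotide-preserving shuffle* (an Euler-path walk over
the order-2 de Bruijn multigraph, the Altschul–Erickson construction):
every shuffle has exactly the original 16-dinucleotide count vector, so
surviving spectral structure reflects ordering, not composition. Each
window gets one shared ensemble of `n_perm` shuffles (5000 at full scale);
every shuffled spectrum is computed once and serves all periods. Per
period $T$ in the test set (8–14 bp by 0.1),

$$P_{T,i} = \frac{1 + \#\{r : Q^*_r(T) \ge Q^*_{obs}(T)\}}{1 + n_{perm}},$$

the plus-one estimator, which is strictly positive and conservative.
$T_{sig}$ is the period with the smallest p-value (ties: larger observed
$Q^*$, then smaller period). Null spectra are computed on the full 2–15 bp
grid so their unit-mean normalization matches the observed spectrum
exactly; only the test subset is scored.

**Why spectra are averaged over four windows.** A single 200 bp window
yields a very noisy spectrum: the maximal normalized power over the test
band routinely reaches 6–8 under the null, which is the same magnitude a
genuine phased-tract cluster produces. Two consequences follow. First, the
minimum of ~60 correlated per-period p-values is not a calibrated
per-window p-value — on background sequence about 11% of windows have
$\min_T P_{T,i} < 0.01$. Second, a per-window test that *is* calibrated
(the single-step max-statistic `p_window`, computed from the permutation
distribution of the maximal $Q^*$ over the test set) has too little power
at 200 bp to be useful on its own. The scan therefore averages the
normalized spectra of four consecutive windows — observed spectra and,
replicate-wise, their independent null ensembles alike — and tests the
averaged 800 bp units (`avg4`, the default). Averaging cuts the null
variance four-fold while leaving a consistent signal intact; with it, the
plain threshold rule $\min_T P_{T,i} < 0.01$ localizes implanted signal
with both precision and recall well above the package's acceptance bars.
Both p-values are always reported per unit: `p_min` (selection default)
and `p_window` (exactly calibrated; `use = "window"` in
`build_segments()`, the better choice when false windows are costlier than
missed ones). Degenerate windows (no motif match) are flagged and excluded.

**Segments.** Adjacent significant units whose $T_{sig}$ falls in the same
period range are concatenated into non-overlapping periodic segments, one
segment set per range. The four default ranges [9.6, 10.3), [10.3, 10.9),
[10.9, 11.6), [11.6, 12.5) bp bracket the solenoidal (<10.5 bp) and
plectonemic (>10.5 bp) sides of the relaxed pitch; they are configurable
throughout, as the literature offers no single canonical split.

## Relating segments to annotation

`jaccard_permutation_test()` compares a segment set against CDS or
intergenic intervals with the Jaccard index $J$ (intersection bp over
union bp, both sets merged first). The null relocates each query interval
to an independent uniform, wrap-free position — the simplest
length-preserving relocation null; overlaps among relocated intervals are
allowed. The one-sided plus-one p-value is reported in the observed
direction (*overlap* if $J$ exceeds the null median, *avoidance*
otherwise), mirroring how overlap versus avoidance profiles are read.

`hypergeom_enrichment()` scores cluster-versus-group gene overlaps with the
upper cumulative hypergeometric tail $P[X \ge k]$. Raw p-values are the
default — enrichment profiles are meant to be comparable across cells —
with a Benjamini–Hochberg column on request.

`cluster_profiles()` is plain agglomerative clustering on Euclidean
distances (`hclust`): Ward's minimum-variance criterion (`ward.D2`) for
entities such as species or CDS, complete linkage for motif columns, cut
at a fixed `k` (4 for species-by-motif SNR matrices, 14 for CDS spectra).

## Where in the codon the signal lives: Q'

`q_prime()` concatenates all CDS (coding strand, genome order; indicator
positions spanning gene junctions are masked) and probes the band power at
one period (`T_probe`, default 11.8 bp — set it near the peak of the
genome under study). Each permutation scheme is applied per CDS, the
concatenation rebuilt, and

$$Q' = P_{\text{after}}(T_{probe}) \,/\, P_{\text{before}}(T_{probe})$$

summarized over 50 replicates (mean and range). The schemes:

* `codon_order` — permute whole codons; destroys the protein and all
  inter-codon phasing, preserves codon usage. A genuine phased signal
  collapses ($Q' \approx 0$).
* `synonymous` — replace each codon uniformly within its synonym class
  (standard genetic code; stops resample within the stop class): protein
  preserved, codon usage randomized.
* `position_I/II/III` — permute the bases of one codon position across the
  CDS; composition at that position is exactly preserved, only its phase
  is destroyed.

Two measurement scales exist and differ in one important way. The ACF is
density-normalized ($\div\,\hat p^2$), so a scheme that lowers the motif
density — synonymous replacement does, because uniform synonym draws
dilute A/T at the third position — has its residual power inflated by
$(\hat p_{before}/\hat p_{after})^4$ relative to schemes that preserve
composition. That is a composition artifact, not retained phasing, and on
position-encoded test data it inverts the expected ranking between
synonymous replacement and position-III permutation. `q_prime()` therefore
measures power on the **covariance scale** by default: the smoothed ACF is
multiplied back by $\hat p^2$, i.e. power of the raw co-occurrence rate,
putting all schemes on one absolute scale (`scale = "density"` gives the
literal density-normalized ratio). Ratios of the unit-mean $Q^*$ itself
are deliberately not used: that normalization is scale-free and cancels
most of the attenuation being measured.

Per-CDS analysis: `per_cds_spectra()` gives each CDS of at least 300 bp
(ACF support out to lag 101 requires it) its own unit-mean spectrum row;
`select_top_periodic()` ranks by maximal *unnormalized* band power over
9.5–13.5 bp — absolute power, because unit-mean rows erase the amplitude
difference between a genuinely periodic CDS and a flat one whose little
power happens to concentrate somewhere — and `cluster_cds_spectra()` Ward-
clusters the retained rows (k = 14 by default), assigning each cluster the
peak of its mean spectrum as its main period $T_{max}$.

## The synthetic data generator

`synthetic_spec()` fixes the study conditions every calibration and test
runs under; its defaults are chosen once:

* **Background**: uniform iid by default, or any first-order Markov
  transition table. First order, because the analysis's own null
  conditions exactly on dinucleotide content — a higher-order background
  would test the generator, not the method.
* **Implants**: arrays of 9 AT-tracts of 4 bp, spaced
  $T_0 + \mathcal N(0, 0.3^2)$ bp (rounded), giving ~100 bp arrays —
  phased-tract clusters of the size the curvature literature describes.
  Arrays are dropped into the implant regions until 40% of the region is
  covered. Each tract is drawn uniformly from the A/T strings of its
  length without TpA, which are exactly $A^j T^{m-j}$. Gaussian spacing
  jitter is a modeling convenience: any small-variance stationary jitter
  leaves the spectral peak in place.
* **Genes** (100 per set, 450–900 bp): codon-sampled, ATG start, single
  terminal stop, no internal stops (repairs happen at codon position II,
  which the bias machinery never uses). Phased tract windows track $T_0$
  along the gene; inside them position III is set to extend an AT2 tract
  with probability 0.8, position I with 0.4, position II with 0.2. The
  monotone III > I > II ordering encodes the empirical structure of the
  coding signal: strongest at the synonymous third position, weakest but
  non-zero at position II. With all three biases at 0 the generator is the
  package's negative control.

What the generator does **not** emulate: codon usage bias and
amino-acid composition of real proteomes, GC skew and replication-strand
asymmetries, repeats and mobile elements, genome-scale heterogeneity of
composition, and operon structure. Passing tests therefore demonstrate
that the statistics recover what they are defined to measure under
controlled conditions — not that any particular real genome is periodic.

## Numerical choices and degenerate inputs

* Period grid step 0.1 bp; peak ties break toward the smaller period;
  degeneracy threshold $10^{-12}$ on total power.
* The plus-one permutation estimator keeps every p-value in $(0, 1]$ and
  conservative.
* Per-window null seeds derive from the scan seed plus the window index,
  so results are independent of evaluation order (and of any future
  parallelization over windows).
* All randomized operations are pure functions of (input, seed); the RNG
  state of the caller is saved and restored.
* Sequences shorter than `k_max + 30` bp cap the lag ceiling at
  window length − 30; CDS shorter than 300 bp are excluded from per-CDS
  spectra; CDS whose spliced length is not a codon multiple are dropped
  with a warning at annotation time (partial and pseudogene CDS are not
  modeled).
* Coordinates are 0-based half-open everywhere inside the package; GFF3
  and GenBank convert at the boundary, BED is native.

## Scale of the shipped checks

The test suite and the acceptance script exercise: period recovery on
100 kb genomes at $T_0 \in \{10.0, 10.5, 11.0, 11.6\}$; null calibration
on 500 shuffle-generated windows at 500 permutations; conservation checks
on 1000 random shuffler inputs; the Q' scheme ranking on the default
100-gene set at 50 replicates; and end-to-end localization on the default
three-region fixture at 1000 permutations. These sizes are the package's
reference conditions; the full-scale analysis of a real chromosome uses
the same code with `n_perm = 5000` and whole-genome input.

## Known limitations

* The windowed scan's spatial resolution is the averaging unit (800 bp by
  default); shorter isolated tract clusters dilute below detectability.
* $Q^*$ is normalized to unit grid mean, so absolute SNR values are
  comparable across genomes only under the same grid and lag window.
* The Jaccard relocation null treats the genome as one unstructured
  interval; chromosome partitions or excluded regions are not modeled.
* Codon permutations act per CDS; signal spanning adjacent genes in
  operons is attributed to the junction mask, not destroyed or preserved
  coherently.
* The synonymous scheme draws synonyms uniformly; codon-usage-preserving
  resampling is out of scope.
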