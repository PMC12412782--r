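---
title: "Inferring Pol II elongation rates with a contiguous least-sum-of-squares scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Pol II elongation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polrate)
```

## The model

A transcription-initiation block (DRB, flavopiridol) stops new RNA
polymerase II from entering gene bodies while engaged polymerases keep
elongating. A nascent-RNA library (Pro-seq/Gro-seq) taken `t` minutes
after the block therefore shows, on each long gene, a read-depleted 5'
region up to some base `d` and essentially unchanged signal beyond it.
Pairing the treated library with an untreated reference from the same
cells and forming per-position normalized count ratios

$$ x_i = \frac{(T_i + c)/N_T}{(R_i + c)/N_R} $$

(`T`, `R` raw counts, `N` library sizes, `c` a pseudocount, default 1)
turns the biology into a one-dimensional change-point problem: ratios are
small up to `d` and near `depth` beyond it. The elongation rate is
`d / t` bp/min.

The only distributional assumption is that the depleted ratios are
stochastically smaller than the intact ones; no parametric family is
imposed, which is the method's advantage over the HMM baseline.

## The split score

For a ratio vector `x[1..L]` and pointer `p`, the score is the total
within-segment sum of squared deviations of `x[1..p]` and `x[p+1..L]`
(segments of size 0 or 1 contribute 0). Minimizing it over `p` is an
exhaustive, exact search over all `L` contiguous 2-partitions — k-means
with `k = 2` under a contiguity constraint, which collapses the `0.5·2^L`
unconstrained candidate set to `L`.

A genuinely open design point: the score could instead sum the two
segments' *variances* (unweighted by segment size). We implemented both
and rejected the variance sum, for a reason worth recording. The two
regions of a drug-blocked gene have very different noise: depleted
ratios hug `c/(R_i + c)` while intact ratios inherit full Poisson
variation. An unweighted variance sum then prefers splitting off a
one-element segment at the quiet end — on this package's own simulation
its base-level accuracy was 0.00 — whereas the size-weighted sum of
squares is exactly the k-means objective the method is defined to be
equivalent to, and localizes the step to within a few bases. Ties in the
score break to the smallest pointer (the earlier transition, i.e. the
conservative, slower rate). Scores are computed from centered values via
cumulative sums in O(L), with an explicit exact-zero rule when both
segments are constant.

## The two-stage bin-expansion search

Scanning a 40 kb gene base by base costs `n` score evaluations and, more
importantly, exposes the argmin to per-base noise. The search therefore
runs twice:

1. **Bin level.** The gene is tiled into `m` bins (`window_num`, default
   40; the first `m − 1` bins have width `floor(n/m)`, the last absorbs
   the remainder so edges stay integral), each bin's ratio computed from
   bin count sums, and the least-SS bin found among `m` candidates.
2. **Base level.** The chosen bin is merged with its downstream neighbor
   (the transition can sit anywhere inside the chosen bin, so the merged
   window always brackets it; for the last bin the region is that bin
   alone), per-base ratios are built over the `≈ 2n/m` bases, and the
   scan repeats to give the final base.

Total work is `m + 2·floor(n/m)` evaluations — 2040 instead of 40 000
for the canonical 40 kb gene — and the bin stage averages away most of
the noise that traps a single-stage scan in local minima. The default
`window_num = 40` balances the two stages for 40–60 kb genes; much
smaller values blur the bin stage, much larger ones hand noisy bases to
stage one.

## Significance

Each gene's bin-level split is tested with a one-sided Mann–Whitney
rank-sum test (depleted segment stochastically *smaller*: the biology
fixes the direction). The exact distribution is used for tie-free
segments of at most 25 values; with ties the exact permutation
distribution over segment assignments is enumerated when there are at
most 2·10^5 of them; otherwise the tie-corrected normal approximation.
P-values are Benjamini–Hochberg adjusted across all tested genes, and a
gene is *significant* when its adjusted bin-level p ≤ `alpha` (default
0.05). The base-level p-value is computed and reported the same way for
comparison but does not gate the call — at base resolution the split is
selected to be extreme, so it serves as a descriptive parity check
between methods, not an independent test. A pointer at the vector end
(empty right segment) yields `NA` and a non-significant call.

Genes enter testing only if at least 40 kb long with reference FPKM
strictly above 1 (`filter_genes`): below that, a 15-minute block either
ran past the TTS or the ratios are too sparse to segment.

## Read counting

Each single-end read (or properly paired fragment; pair strand taken
from mate 1, the directional-ligation convention) contributes one count
at its 3'-most aligned base in gene orientation — the polymerase active
site in a run-on assay. `five_prime` and `full_overlap` conventions are
available; MAPQ < 10 is dropped by default; no deduplication is applied.
The library size is the genome-wide count of qualifying reads, computed
once per BAM and cached. Gene-relative coordinates are 1-based with base
1 at the TSS (interval start for `+` genes, interval end for `-` genes).

## The HMM baseline

The comparison method is a two-state Gaussian HMM over the same ratio
vectors, fitted by Baum–Welch with scaled forward–backward recursions
and decoded by Viterbi, inside the identical two-stage framework.
Numerical choices (the literature leaves them open): state means seeded
at the 25th/75th percentiles, falling back to the data range when those
coincide (as they do for strongly unbalanced steps); shared initial
variance floored at 10⁻⁶ to prevent emission collapse; sticky transition
seed (0.9/0.1); tolerance 10⁻⁶ on the log-likelihood, at most 1000
iterations; states relabeled after fitting so state 1 is the low-mean
(depleted) state. The pointer is the end of the leading depleted block;
a path that does not begin depleted, never switches, or a degenerate fit
(constant input) yields an invalid call rather than an error, since one
depleted prefix is the only admissible biology. Significance of the HMM
pointer reuses the same rank-sum machinery so the two methods'
significance proportions are directly comparable.

## The simulator and what a green test establishes

`simulate_dataset` draws, per gene, a length uniform on 40–60 kb (the
scale the length filter admits), reference counts Poisson(`base_rate`)
per base (default 0.5 reads/base, a realistic depth for a well-covered
run-on library after filtering), and treatment counts
Poisson(`base_rate · depth · difference`) up to the true transition
`floor(distance·n + 0.5)` (ties rounded up) and
Poisson(`base_rate · depth`) beyond; negative mode draws intact depth
everywhere and records no truth. Library sizes are the dataset's own
totals, so FPKM filtering is self-consistent. A negative-binomial option
(`overdispersion`) exists for sensitivity checks but is off by default.

The generator emulates the *structure* of a block experiment — uniform
reference coverage, a sharp per-gene depletion boundary, library-size
imbalance — and deliberately not its nuisance features: mappability
gaps, fragment-length structure, promoter pause peaks, expression
heterogeneity between genes, or correlated noise from shared read
subsampling. A green accuracy test therefore establishes that the
two-stage scan localizes a genuine abrupt ratio change under Poisson
noise at realistic depth, not that real libraries are this clean; the
accuracy numbers on synthetic data sit near the top of the plausible
range for that reason. Scoring follows the ≤ 50 bp rule with *all*
simulated genes in the denominator (a non-significant call on a positive
gene counts against accuracy — the stricter reading).

## Assistant statistics

* **Pause index**: promoter density (TSS ± 1 kb, so half the window lies
  upstream of the gene and is read from the track's upstream flank) over
  body density; the body runs from the promoter's downstream edge to the
  TTS so the two regions are disjoint. Genes whose promoter window or
  body overlaps another gene are excluded rather than reported with
  contaminated densities; an empty body raises a flag, not a division.
* **Metagene**: each gene's TSS–TTS FPM vector is resampled to 2000
  positions by proportional coordinate mapping with mean aggregation
  (position `j` averages bases `floor((j−1)n/L)+1 … floor(jn/L)`); the
  matrix is capped at its 99 % quantile so single outlier positions do
  not set the color/axis scale.
* **k-mers**: overlapping windows on the sense strand, pseudocount-
  smoothed frequencies, ratio between sets sorted descending; the
  ranking is antisymmetric between the two sets by construction.
* **Exon density** is merged-exon count per kb (the unit is a package
  choice; merging makes it transcript-set independent). **Quantile
  split** puts rates strictly below the 50 % quantile in cluster 1;
  cluster comparisons use two-sided rank-sum tests since direction is
  not fixed a priori there.

## Known limitations

Single change point per gene (no multi-wave or partial-block modeling);
no replicate-aware joint model or uncertainty interval on the rate; the
rate distance is measured from the TSS with no promoter-pause offset;
FPKM normalization assumes comparable library composition between
treatment and reference. The bin-tiling remainder rule means the
candidate-count identity `m + 2·floor(n/m)` is exact when `m | n` and
off by the remainder width otherwise.
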