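# polrate

Inference of RNA polymerase II transcription **elongation rates** from
drug-block nascent-RNA sequencing (Pro-seq / Gro-seq), for labs studying
transcription dynamics.

## The problem and the method

When cells are treated with an initiation blocker such as DRB or
flavopiridol, polymerases already in the gene body keep elongating while
no new ones enter. After `t` minutes, each gene shows a polymerase
**depleted** 5' region followed by an **intact** downstream region; the
boundary (the depleted/intact *transition point*, at distance `d` bp from
the TSS) gives the elongation rate `v = d / t` in bp/min.

`polrate` locates the transition by change-point detection on the
normalized treatment/reference coverage ratio of each gene. For a ratio
vector `x[1..L]`, every pointer `p` splits it into `x[1..p]` and
`x[p+1..L]`, scored by the within-segment sum of squares

```
SS(p) = sum_{i<=p} (x_i - mean(x[1..p]))^2 + sum_{i>p} (x_i - mean(x[p+1..L]))^2
```

The least-SS pointer is exactly the best contiguous 2-partition — k-means
with k = 2 constrained to contiguous clusters, searched exhaustively over
all `L` candidates rather than greedily over `0.5 * 2^L`. The search runs
in a two-stage *bin-expansion* framework: the gene is first divided into
`m` bins (default 40) of its per-base ratios, the least-SS bin found,
then that bin merged with its downstream neighbor and rescanned base by
base — `m + 2(n/m)` score evaluations instead of `n` (2040 instead of
40 000 for a 40 kb gene), and the coarse stage averages away per-base
noise. Significance of a split is a one-sided Mann–Whitney test (depleted
ratios stochastically smaller), Benjamini–Hochberg adjusted across genes.
A two-state Gaussian HMM (Baum–Welch + Viterbi) is included as the
traditional baseline under the same two-stage framework.

The package also provides the assistant statistics used alongside rate
inference — promoter-proximal **pause index** (density TSS±1 kb over gene
body), **metagene** compression of TSS–TTS profiles to a common length
with 99 %-quantile capping, GC content, k-mer enrichment between gene
clusters, exon density — and a Poisson count **simulator** with an
accuracy harness (a call is *correct* when the inferred base is ≤ 50 bp
from the simulated truth).

## Worked example

Simulate a 15-minute block experiment (150-gene scale shrunk to 5 for
display): reference coverage ~Poisson(0.5)/base, treatment depleted to
2 % of intact signal over the 5' half of each gene.

```r
library(polrate)
ds <- simulate_dataset(sim_config(n_genes = 5, seed = 42))
calls <- infer_rates(ds$genes, ds$treatment_tracks, ds$reference_tracks,
                     rate_config(window_num = 40, treatment_minutes = 15))
calls[, c("gene_id", "n", "transition_bin", "transition_base",
          "q_bin", "significant", "rate_bp_per_min")]
#>       gene_id     n transition_bin transition_base     q_bin significant rate_bp_per_min
#>  sim_gene_001 58752             20           29377 1.209e-11        TRUE            1958
#>  sim_gene_002 49289             20           24648 1.209e-11        TRUE            1643
#>  sim_gene_003 41251             20           20627 3.393e-08        TRUE            1375
#>  sim_gene_004 55505             20           27751 3.393e-08        TRUE            1850
#>  sim_gene_005 48825             20           24410 1.209e-11        TRUE            1627

evaluate_accuracy(calls, ds)
#> <accuracy_report> 5/5 correct (accuracy 1.000), 5 significant
```

Every gene's transition lands within a few bp of the simulated truth
(deltas above were +1, +3, +1, −2, −3 bp), each bin-level call is
significant after BH adjustment, and the rates (`transition_base / 15`)
recover the stated half-gene depletion. Real data enter through
`calrate(treatment_bam, reference_bam, genes, ...)` with gene models from
`read_gene_models()` (BED6/BED12/GTF); an equivalent command-line surface
lives in `inst/cli/polrate` (subcommands `rate`, `pause`, `metagene`,
`structure`, `simulate`, `evaluate`).

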