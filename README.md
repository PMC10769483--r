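# mmselect

Multicompound–multitarget selectivity scoring for kinase inhibitor mixtures.

Kinase inhibitors are rarely clean: most bind dozens of off-target kinases
at pharmacologically relevant concentrations. `mmselect` asks a question the
classical per-compound selectivity metrics cannot: *what is the most
selective way — possibly a mixture of several inhibitors — to reach potent
inhibition of a chosen target (or target set)?* Because competitive
occupancies add across compounds, a combination dosed so that its
**cumulative** on-target activity reaches the potency threshold dilutes each
component, and with it every private off-target, below where any single
compound would sit. The package finds and scores such combinations from an
ordinary compound × kinase potency matrix.

## The model

Activity is fractional target occupancy. For a mixture of `n` competitive
inhibitors at concentrations `I_j` with affinities `K_ij` against kinase
`i`, the cumulative occupancy is

    I_T = S / (1 + S),    S = sum_j I_j / K_ij

reported as a percentage, and the mixture's equivalent combination affinity
(its predicted combination EC50 at fixed molar ratio) is

    K_eq = (1/I_T − 1) · sum_j I_j .

Affinities (K_d / K_i / K_d^app in nM, treated equivalently) are projected
onto the activity scale at a 1 µM reference frame via
`activity = 100 / (K/1000 + 1)`, so 100 nM ↦ ~91%, 1 µM ↦ 50%, and the
90% potency threshold corresponds to 111 nM.

Selectivity of a mixture dosed at threshold on-target activity is scored as
the **Jensen–Shannon distance** (base-2, so the score lives in [0, 1])
between two 20-bin histograms over the 0–100% activity axis: the mixture's
Gaussian-smoothed off-target activity distribution, and a left-skewed
*penalty distribution* (Poisson-tail or beta shaped, mode pinned at 100%
activity) that encodes which off-target activity ranges the user cares
about. Score 1 means no off-target activity in any penalized range.
Component concentrations are optimized by a branch-and-bound hill climb
(pairwise `R1`-fold variations, re-dilution onto the threshold each step),
and the best combination is compared with the best single inhibitor across
five technical replicates (two-sample t-test plus an absolute ΔJSD cutoff
of 0.001).

## Worked example

Three inhibitors share a target (all at K = 111 nM, i.e. exactly 90%
single-compound activity at 1 µM) and each carries one private off-target
at the same affinity. Any single compound dosed to 90% on-target leaves its
off-target at 90%; the equimolar trio needs only a third of each dose, so
every off-target drops to 100·9/(3+9) = 75%.

```r
library(mmselect)

K <- activity_to_affinity(90)              # 111.1 nM
v <- matrix(NA_real_, 3, 4,
            dimnames = list(c("c1", "c2", "c3"), c("T", "o1", "o2", "o3")))
v[, "T"] <- K; v[1, "o1"] <- K; v[2, "o2"] <- K; v[3, "o3"] <- K
m <- potency_matrix(v, "affinity")

res <- run_mms(m, target_spec("T"), penalty_preset("tight", seed = 1),
               optimizer_config(max_i = 3), seed = 42)
res
#> <mms_result> verdict: combination_better
#>   best single: c1 (mean JSD 0.8035)
#>   best combo:  c1 + c2 + c3 (mean JSD 0.8647, dJSD +0.0612, p = 9.83e-10)
#>   reproducibility: 100%
```

The trio scores higher because its pooled off-target histogram sits at 75%
activity, further from the penalty mass concentrated near 100%, while every
single inhibitor leaves an off-target at 90%. The verdict is
`combination_better` only when the improvement is both statistically
significant across replicates and at least 0.001 in absolute score.

A command-line wrapper is installed as `exec/mms`
(`mms run --matrix m.csv --targets FLT3 --penalty tight,medium --seed 7 ...`),
with subcommands `run`, `score`, `simulate`, `convert` and
`compare-metrics`.

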