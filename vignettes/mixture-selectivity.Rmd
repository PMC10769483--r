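---
title: "Scoring and optimizing kinase-inhibitor mixture selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and optimizing kinase-inhibitor mixture selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmselect)
```

## The problem

A kinase inhibitor's usefulness as a probe or lead depends on how cleanly it
engages its target against the background of ~500 human kinases. Classical
selectivity metrics score single compounds: the Gini coefficient and S-score
describe a compound's whole activity profile with no notion of which kinase
is *the* target, while relative metrics (partition-index-style scores, here
the relative selectivity factor) divide on-target activity by total
activity. None of them answers the design question this package addresses:
given a potency matrix and a target (or set of targets), what dosing of
which compound — or which *mixture* of compounds — achieves potent on-target
engagement with the least objectionable off-target profile?

Mixtures can genuinely win. Competitive occupancies are additive on the
`S = I/K` scale, so several inhibitors sharing a target can each be dosed at
a fraction of their single-agent concentration while their *cumulative*
on-target occupancy still reaches the potency threshold. Each component's
private off-targets are then engaged at that diluted concentration. In the
idealized case of `n` equally potent inhibitors with disjoint off-targets,
dosing equimolar to 90% cumulative on-target activity puts every off-target
at `100·9/(n+9)` percent — 90, 81.8, 75 for n = 1, 2, 3 — a closed form the
test suite checks to machine precision.

## The occupancy model

All potencies are handled as dissociation/inhibition constants in nM
(`K_d`, `K_i`, `K_d^app` treated equivalently). A mixture's occupancy of a
kinase is the Langmuir-type competitive form

\[
I_T \;=\; \frac{\sum_j I_j/K_{ij}}{1 + \sum_j I_j/K_{ij}} \times 100\%,
\]

an approximation that deliberately ignores ATP-concentration effects,
enzyme depletion and binding kinetics; it describes equilibrium target
engagement, not cellular phenotype, and no pharmacokinetic interpretation of
optimized concentrations is intended. The equivalent combination affinity
`K_eq = (1/f − 1)·ΣI_j` (with `f` fractional occupancy) is invariant under
rescaling the total dose at a fixed molar ratio and reduces to the
component's own `K` for a single compound; for an equimolar mixture it is
the predicted combination EC50. For compounds with EC50s of 82 nM, 4.6 µM
and 1.8 µM it predicts:

```{r}
equivalent_affinity(mixture(c("a", "b", "c"), c(1, 1, 1)),
                    c(a = 82, b = 4600, c = 1800))
```

Affinity matrices are projected onto a percent-activity scale at a
*reference frame* of 1 µM (configurable): `activity = 100/(K/ref + 1)`.
The reference frame standardizes inputs and sets the meaning of the potency
threshold — at 1 µM, the default 90% threshold corresponds to a 111 nM
affinity; at a 100 nM frame compounds would need to be tenfold more potent.
Activity-valued inputs (single-concentration screens, 0–100% displacement at
a stated concentration) are inverted to pseudo-affinities through the same
formula, with saturated values of exactly 100% clamped to 99.995% first
since zero affinity is not representable. Missing cells are treated as no
detectable binding: they contribute zero occupancy, but the kinase remains
in the off-target universe, where its zero activity adds mass to the lowest
histogram bin. This keeps off-target distributions comparable across
sparsely and densely measured compounds.

## Penalty distributions

Not all off-target activity matters equally. The user encodes what matters
as a *penalty distribution*: a probability distribution over the 0–100%
activity axis with its mode pinned at 100% and a left-skewed tail, built by
Monte-Carlo sampling (100,000 draws by default) from one of two shapes:

* **Poisson left tail** — counts `k ≤ µ` from Poisson(µ), mapped one
  activity-point per count, `x = 100 − (µ − k)`. The spread scales as
  `√µ`: µ = 200 ("tight") effectively ends near 50% activity, µ = 700
  ("medium") reaches ~20%, µ = 1200 ("broad") covers the whole axis. The
  count→activity mapping is a unit-scale choice of this package; it is the
  simplest mapping that pins the mode at 100% and reproduces those widths.
* **Beta** — `Beta(α, β)` scaled to 0–100; `α > 1, α > β` gives the
  required right-edge mode.

Both are binned at 5% activity — twenty bins, `[0,5) … [95,100]`, the last
bin closed — a bin width coarse enough to absorb sampling noise and fine
enough to resolve meaningful activity differences. An additional
*high-off-target penalty* mass (default 0.1, raised to ~0.3 in multi-target
work) is added to the `[95,100]` bin before renormalization; it compensates
for the activity scale's logarithmic compression near saturation, where a
52 nM and a 5.2 pM off-target differ by four orders of magnitude in affinity
but only 5 activity points (95.05% vs 99.99%). Whether that extra mass
should be spread inside the 95–100% range is ambiguous; it is applied to the
single final bin here.

We recommend running every analysis under at least two penalties (tight plus
medium or broad) unless the relevant off-target range is known; the
configuration layer warns when only one is configured. A score of exactly 1
under a tight penalty triggers a warning too — it may only mean that no
off-target activity falls inside the narrow penalized range.

## Scoring

At scoring time the mixture is diluted (geometric steps of `R2 = 1.1` by
default) onto the on-target threshold, its off-target activities are
computed, and each is replaced by `samples_per_kinase = 100` draws from a
Gaussian centred on it with variance 2.5 (complementing the 5% bins);
samples are clipped to [0, 100] — clipping rather than discarding or
reflecting keeps every kinase's weight constant. The pooled, binned,
normalized histogram is compared to the penalty by the Jensen–Shannon
*distance* (square root of the divergence) with base-2 logarithms, which
makes the score range exactly [0, 1]: 0 for identical distributions, 1 for
disjoint supports, higher = more selective. An empty off-target universe
scores 1 by convention. Mutant kinases (flagged explicitly or by a
parenthesized-name pattern like `FLT3(D835Y)`) may be targets but are never
counted as off-targets.

The injected Gaussian noise is also the method's uncertainty model: five
technical replicates are run with fresh noise and a freshly resampled
penalty each, and a combination is declared better than the best single
inhibitor only if a two-sided two-sample Student's t-test across replicates
gives p < 0.05 **and** the mean score improvement is at least 0.001 (an
absolute cutoff that discards statistically clean but functionally
meaningless gains). Reproducibility — the percentage of replicates whose
rank-1 compound set matches the modal one, ties broken lexicographically —
is reported as a stability diagnostic, not a validity measure.

## Concentration optimization

Each feasible combination is optimized by a greedy branch-and-bound climb:
start equimolar at the reference concentration, dilute onto the threshold;
each round, vary every unordered pair of components `R1`-fold (default 5) in
both orientations (one up, one down — both orientations are generated to
avoid a directional bias the procedure would otherwise inherit from
component ordering), clamp to the concentration bounds, re-dilute each
candidate onto the threshold, score, keep the best, cull the rest; stop when
no candidate improves the incumbent by more than 1e-6. Ties are broken
toward lower total concentration, then lexicographic compound order.

Within one optimization all scorings share a single noise realization
(derived from the replicate seed). This makes the objective deterministic,
so candidate comparisons are paired and the incumbent score is
non-decreasing by construction — the property the test suite asserts over
100 random toys. Fresh noise enters *between* technical replicates, which is
where the method models measurement uncertainty.

`R1` trades precision for speed: pair moves change a concentration ratio by
`R1²`, so the default 5 resolves ratios only to 25-fold steps, which is
fine for ranking combinations but coarse for pinpointing the optimal ratio.
Where the tests compare the optimizer against an exhaustive 61-point
log-grid over the ratio (steps of ~1.26×), they run it at `R1 = 1.3`, the
precision end of the useful 2–5 range scaled down to the grid's own
resolution, and raise the toy's pooled noise depth to what a ≥50-kinase
universe receives at defaults (2500 draws across 2 off-targets) so sampling
jitter cannot stall the climb between grid points. Activity-kind matrices
skip concentration optimization entirely and stay equimolar: near the
threshold, single-concentration screening values are too imprecise for
dilution ratios derived from them to be meaningful.

Combination feasibility — can the subset reach the threshold at *every*
target with components at or below `max_conc`? — gates enumeration. In
multi-target runs the eligible pool admits compounds potent against at
least one target (a compound weak on every target alone can still be the
piece that completes a mixture); mixtures below threshold are scaled up
rather than discarded, so feasibility is decided by the concentration
ceiling alone. By default no ceiling is imposed (screening mode); a 1 µM
ceiling is the conservative choice for validation-oriented runs where
solubility matters.

## Synthetic panels and simulation studies

The simulation engine generates everything the tests and trend studies
need, with no external data:

* **Parent profiles** — 20-bin activity distributions from which panels are
  bootstrapped i.i.d. The screening-like default places 80% of its mass
  below 5% activity with a geometrically decaying mid-range (decay 0.72 per
  bin) and a 2% potent-hit mass, approximating the shape of a large,
  relatively selective compound screen; reduced-selectivity and
  least-selective variants mix the non-hit bins with a uniform distribution
  (weights 0.35 and 0.75) while holding hit probability fixed, so threshold
  reachability is comparable across profiles; a binary profile draws only
  inactive (< 5%) or potent (> 95%) activities. These are parameterized
  shapes, not any published panel's exact average.
* **Set-size scans** — panels of 50/150/600 compounds × 100 kinases, every
  kinase taken as a single target in turn. Larger panels yield more
  selective best singles (better extremes from more draws) and a larger
  percentage of targets where a combination significantly beats the best
  single. The scan default is pairs only (`max_i = 2`): the monotone trends
  are unaffected by allowing trios, and pairs keep the full
  3-sizes × 3-seeds scan at desk scale (the suite's scan runs ~10 minutes
  on one CPU). These are stochastic trends, asserted after aggregating over
  three panel seeds. Note a ceiling effect the binary profile makes acute:
  with ~2 hits per compound, large panels almost surely contain, for most
  targets, a single inhibitor with *no* off-target hit (or one so much
  weaker than its on-target potency that dilution pushes it below every
  penalized range). Such singles score 1, or within the 0.001 functional
  cutoff of it, and no combination can significantly improve on them — so
  the fraction of combination-improvable targets rises with panel size only
  until single-inhibitor selectivity saturates, and can dip slightly
  beyond that point.
* **Fold-error propagation** — equimolar mixtures of 1–4 components with
  affinities drawn log-uniformly from 1–1000 nM (the potency-eligible
  range), each component's affinity perturbed by a factor uniform on [1, 4]
  applied as multiply-or-divide with equal probability (the symmetric
  reading of "randomly varied"); 1000 cases per size. Single-compound
  fold-errors reproduce the input distribution exactly; component errors
  partially cancel in the harmonic-mean combination affinity, so the median
  fold-error is non-increasing in combination size.

What passing these simulated tests does *not* show: real panels have
correlated off-target structure (chemotype families, kinase-family
cross-reactivity), assay-to-assay systematic shifts, and sparsity patterns
that are anything but i.i.d. The simulations validate the machinery and its
qualitative behavior, not dataset-specific score values.

## Numerical choices and degenerate inputs

* Binning: half-open `[0,5) … [90,95)`, closed `[95,100]`; activity 100 is
  representable, bin probabilities sum to 1 within 1e-12.
* JSD: `0·log 0 = 0`; the divergence is clamped at [0, 1] before the square
  root against floating-point drift.
* Dilution meets the threshold within one `R2` step from above; a mixture
  already exactly at threshold is returned unchanged; all-zero mixtures and
  unreachable targets return an explicit infeasible flag rather than
  erroring mid-pipeline.
* Reproducibility and optimizer tie-breaks are lexicographic on sorted
  compound IDs, making every reported result deterministic under a fixed
  master seed; per-replicate and per-combination seeds are derived from the
  master seed by hashing, so results do not depend on evaluation order.
* Degenerate replicate vectors (zero variance on both sides) short-circuit
  the t-test to p = 1: identical score sets are never "significant".
* The Gini coefficient uses the sorted-rank identity, `O(n log n)`, exact
  for ties.

## Limitations

Scores inherit every limitation of the input matrix: biochemical or
kinobead potencies do not capture cellular context, regulatory domains, or
kinetics, and activity-valued screens carry single-concentration noise. The
occupancy model assumes purely competitive, mutually independent binding.
Optimized concentrations are equilibrium target-engagement statements, not
doses. And the greedy climb is a heuristic: for three or more components the
concentration landscape can hold local optima the pairwise moves cannot
escape; exhaustive search is used as a cross-check only where it is
tractable (two components, few off-targets).
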