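---
title: "Estimating VAS-based 15D value algorithms: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating VAS-based 15D value algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vas15d)
```

## The model

The 15D describes health as a vector $\mathbf{l} = (l_1, \dots, l_{15})$ of
function levels, $l_j \in \{1, \dots, 5\}$. The package estimates and applies
additive value algorithms

$$V_H(\mathbf{l}) = 1 - \sum_{j=1}^{15} T_{j, l_j}, \qquad T_{j,1} = 0,$$

where $T_{j,i} \ge 0$ is the disutility decrement for being at level $i$ on
dimension $j$. Additivity is the standard simplification from multi-attribute
utility theory for an instrument of this size: with $5^{15}$ states, direct
valuation of a representative state sample is infeasible, so each level of
each dimension is valued separately and the only whole-state judgement
retained is the "pits" task (level 5 on every dimension), which is also the
one measurement that can capture interactions between levels. Structural
independence of the 15 dimensions is assumed, not tested.

Estimation proceeds in four steps from two VAS task types, each step a
separate function so the intermediate quantities remain inspectable:

1. **Weighted level means** (`weighted_level_means`). For each dimension $j$
   and level $i \in \{2,\dots,5, \text{dead}\}$, the post-stratification
   weighted mean $\bar s_i^j$ of the raw 0–100 VAS scores. Level 1 is 100 by
   task design.
2. **Relative scores** (`relative_scores`).
   $S_{j,i} = (100 - \bar s_i^j) / (100 - \bar s_\text{dead}^j)$, each
   dimension anchored at *its own* mean dead score. The formula subscripts
   the dead mean by dimension, so no pooling of dead scores across tasks is
   done. $S_{j,i} > 1$ is meaningful (a level rated below being dead) and is
   not clipped.
3. **Pits anchor** (`pits_estimate`).
   $v_\text{pits} = (100 - \bar s_\text{pits}) / (100 - \bar s_\text{dead})$
   over the pits task's complete responses, its own dead mean in the
   denominator. $v_\text{pits} > 1$ means the worst state is on average worse
   than dead.
4. **Rescaling** (`build_algorithm`).
   $\omega = v_\text{pits} / \sum_j S_{j,5}$ and $T = \omega S$. This bounds
   values at 1 for perfect health and $1 - v_\text{pits}$ for the pits state,
   and makes $\sum_j T_{j,5} = v_\text{pits}$ an exact identity. $\omega$ is
   always computed from the data, never fixed: for the packaged Norwegian
   table it evaluates to 0.113.

The anchoring choice matters: summing the level-5 decrements *without* the
pits rescaling would assign the worst state the sum of fifteen separately
elicited worst-level disutilities — an implausibly wide range — whereas the
pits task anchors the range in a direct empirical judgement of the worst
state against being dead, which is what the QALY model's ratio scale (dead
at zero) requires.

## Post-stratification weighting

Weights make each task's completers representative of the general adult
population: a completer in demographic cell $c$ receives
$w_c = P_\text{pop}(c) / P_\text{sample}(c)$, computed separately per task
over that task's completers only (16 weight sets: 15 within-dimension tasks
plus the pits task). Two cell definitions are supported:

* `scheme = "crossed"` (default): cells are the full cross-classification of
  gender × age group × education. This requires joint population counts.
* `scheme = "marginal"`: the product of one-variable population/sample
  ratios. For a single variable this matches the population margin exactly;
  for several it is a deliberate approximation — iterative raking is out of
  scope.

The packaged population table (`norwegian_population()`) carries marginal
counts only, so it supports marginal weighting exactly and crossed weighting
only with a user-supplied joint table. Whether the original weighting
crossed or raked its three variables is not documented in the available
material; the flag records that estimates may differ between the two.

Degenerate cells are handled deterministically: a crossed cell with
population mass but no completers is collapsed by merging adjacent education
categories first, then adjacent age bands, before failing; every collapse is
logged on the result. No weight trimming is applied by default (an optional
cap exists). A respondent missing any demographic variable used for a task's
weights is excluded from that weighting and from estimation, and counted in
the estimation log. The pits task is weighted by gender × age only, because
the face-to-face pits collection asked only for age and gender; the
estimation log records this.

## Tunable parameters

| Parameter | Where | Default | Units / rationale |
|---|---|---|---|
| `min_dead_gap` | Steps 2–3 | 1 | VAS units; requires $100 - \bar s_\text{dead} \ge 1$ so a dead mean near 100 is an error (explosive denominator), never a silent clamp |
| `complete_cases` | Step 1 | `FALSE` | by default a respondent contributes to exactly the level cells they answered; `TRUE` drops partially answered tasks, since the original item-level missingness rule is undocumented |
| `scheme`, `vars`, `pits_vars` | weighting | crossed; gender, age, education; gender, age | see above |
| `max_weight` | weighting | none | the source procedure mentions no trimming |
| `digits` | export | 4 | published precision; no rounding happens inside the pipeline, only on export |

Raw scores outside $[0, 100]$ are rejected at parse time; the VAS is bounded
and winsorizing would silently change means.

## The synthetic-data generator

No respondent-level valuation data are public, so validation rests on a
generator whose statistical structure is exactly what the estimator assumes,
with known ground truth. For respondent $r$ and task $j$: "being dead" is
placed at $d \sim \text{TruncNormal}(\mu_\text{dead}, \sigma)$ on $[0, 99]$,
and level $i$ is scored $100 - S_{j,i} (100 - d) + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$, clamped to $[0, 100]$; the pits task uses
$v_\text{pits}$ in place of $S$. At $\sigma = 0$ this construction inverts
Steps 2–3 exactly, which is the basis of the round-trip tests: noise-free
generation followed by estimation reproduces the truth table to floating
precision, with or without weighting.

Defaults emulate the study conditions the package is built around: 2,256
within-dimension respondents and 120 pits respondents; demographics drawn
independently from the 2010 Norwegian population margins (the joint
distribution is not published; a joint table can be supplied); a pits point
mass at zero of 48/118 for respondents who place both the pits state and
dead at the bottom of the scale; a 2% per-field missingness rate (the
documented pits exclusion was 2 of 120). Response noise defaults to
$\sigma = 10$ VAS units — nothing is documented about response error, so
this is an assumption, configurable and varied in the tests.

Two generator choices deserve explanation:

* **Dead location is per task**, default `c(within = 15, pits = 40)`. The
  pits value cannot sit below 15 or so: with non-negative pits scores, a
  pits disutility of 1.5158 forces the mean dead score above
  $100 (1 - 1/1.5158) \approx 34$, otherwise the construction truncates at
  zero and the anchor is unrepresentable. 40 is the lowest round value
  consistent with the published anchor; the config warns about incompatible
  combinations rather than silently biasing the pits estimate.
* **What makes weighting matter is subgroup preferences, not dead
  placement.** Because Step 2 is a ratio of weighted means and
  $E[100 - s_i] = S \cdot E[100 - d]$, any distribution of dead placements
  cancels from $S$ (exactly at zero noise). Heterogeneous dead scores alone
  therefore cannot create weighting bias. The generator instead supports
  `s_scale_by_education`, a multiplicative preference shift for chosen
  education groups; the weighting-consistency test over-represents a shifted
  subgroup and checks that weighted estimation recovers the
  population-mixture truth where unweighted estimation does not.

What the generator does **not** emulate, and what passing tests therefore do
not establish about real data: VAS response heaping at multiples of 5/10 and
end-aversion; mode effects between web and postal administration; any
dependence of preferences on unmodelled covariates; non-normal response
error. All randomness flows from one seed through fixed sub-stream offsets
(demographics, within responses, pits responses), so any part of a study is
independently reproducible.

## Numerical choices and degenerate inputs

* Consistency of an algorithm table ($\sum_j T_{j,5}$ vs. its stored
  `v_pits`) is checked at tolerance $2 \times 10^{-3}$ on read — wide enough
  for a table rounded to 4 decimals (15 cells × half-ULP), tight enough to
  catch real corruption. Algorithms built in memory are checked at
  $10^{-8}$.
* Ranking ties in `algorithm_summary` break by canonical dimension order;
  percentile bins are equal-count with the remainder spread over leading
  bins (the binning behind published percentile curves is not specified, so
  a deterministic convention is documented instead).
* Empty estimation cells (a dimension × level with no usable response), a
  dimension missing from the data entirely, an empty completer set, and an
  all-missing pits task are hard errors naming the offending unit —
  the pipeline never interpolates silently.
* Scoring states with missing levels is rejected by default
  (`batch_score(..., permissive = TRUE)` scores the valid rows and returns
  `NA` for the rest with a warning); the published algorithm is defined only
  for complete states.
* The packaged table is applied at its published 4-decimal precision;
  algorithms estimated in-session keep full precision until export.

## Validation problem sizes

The test suite validates exact recovery at 120–300 respondents (where
exactness is scale-free), margin matching at $n = 10^4$ demographic draws,
and estimator convergence at $n \in \{250, 1000, 4000\}$ respondents per
task with $\sigma = 10$, seed fixed, checking that per-cell RMSE decreases
monotonically in $n$. RMSE does not shrink at the full $1/\sqrt{n}$ rate at
the largest $n$ because clamping to the VAS bounds induces a small bias
floor; the round-trip tests quantify the variance part, the bias is bounded
by the truncation effect and vanishes in the noise-free limit.

## Known limitations

* VAS is the sole elicitation method; its valuations are not choice-based
  trade-offs, and the relative weight of dimensions arises from level-vs-dead
  comparisons rather than direct trade-offs between dimensions.
* The additive model assumes structural independence of the dimensions; the
  pits state is the only interaction-sensitive measurement and it enters
  only through the range.
* Marginal weighting with several variables matches no margin exactly;
  raking is intentionally out of scope.
* The packaged population margins describe the 2010 adult population (ages
  16+ for the population vs. 18+ for the sample in the youngest band, a
  discrepancy inherited from the source tables).
* The generator's truncated-normal noise model is an assumption of
  convenience, not an empirical fit.
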