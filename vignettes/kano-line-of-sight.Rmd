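---
title: "Kano survey evaluation and in-line-of-sight prioritization: methods"
author: "kanosight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kano survey evaluation and in-line-of-sight prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanosight)
```

## The model

A Kano item pairs a *functional* question (reaction to an attribute
being present) with a *dysfunctional* question (reaction to it being
absent), both answered on the same 5-level scale (`delighted`,
`expected`, `neutral`, `tolerated`, `dislike` in the package's canonical
tokens), plus a 5-level relevance question. Each complete answer pair
maps through the classical 5 × 5 matrix (`kano_matrix()`) to one of six
categories: attractive (A), one-dimensional/performance (P), must-be
(M), indifferent (I), reverse (R), questionable (Q). Over the 25 cells
the matrix allocates Q:4, A:3, P:1, M:3, I:7, R:7 — a property the test
suite verifies by full enumeration. A pair with either half absent is
*not categorizable*; the package never imputes, and tallies such pairs
separately (`n_missing`).

Per attribute, the tally of categories is condensed in three ways:

* **Mode rule** — the most frequent category.
* **If-then rule** — if P+A+M > I+R+Q, the argmax over {P, A, M};
  if smaller, the argmax over {I, R, Q}.
* **Timko indices** — Better = (A+P)/(A+P+M+I), the relative value of
  meeting the requirement, and Worse = −(P+M)/(A+P+M+I), the relative
  cost of not meeting it. R and Q are excluded. Optionally both are
  multiplied by the attribute's mean self-stated importance.

The indices place each attribute at a coordinate (Worse, Better) in the
rectangle [−1, 0] × [0, 1]. Importance weighting shrinks coordinates
toward the origin, which separates attributes whose raw indices nearly
coincide.

## The in-line-of-sight ranking

When all attributes fall into one category (a common outcome for
carefully pre-vetted quality principles, which respondents treat as
"taken for granted" — the must-be corner), none of the rules above
yields a priority order. The in-line-of-sight method ranks attributes by
proximity to the *extreme corner* of a chosen quadrant, the point of
view (POV): must-be = (−1, 0), attractive = (0, 1), one-dimensional =
(−1, 1), indifferent = (0, 0). For each attribute:

1. `d` — the Euclidean distance from the (weighted) coordinate to the
   corner, in [0, √2];
2. `α` — the angle in degrees at the corner between a fixed quadrant
   edge (the α = 0 reference ray) and the line of sight to the
   attribute, in [0, 90];
3. `f = d + (α/90) · 0.05 · √2` — the ranking coefficient; attributes
   are ranked by ascending `f`.

The angle term is deliberately capped at 5% of the maximal in-square
distance, so it acts as a secondary criterion: it discriminates between
attributes at (nearly) equal distance but cannot overturn a distance
difference larger than ≈ 0.0707.

### Angle conventions

Each POV fixes the direction in which α *increases* (argument
`angle_toward` of `corner_pov()`); the α = 0 ray is the quadrant edge
toward the other adjacent corner. Defaults:

| POV | α = 0 ray points toward | α grows toward |
|---|---|---|
| must-be | indifferent (the Worse axis) | one-dimensional |
| attractive | indifferent (the Better axis) | one-dimensional |
| one-dimensional | attractive | must-be |
| indifferent | attractive | must-be |

For the must-be POV this gives α = arctan(Better / (1 + Worse)): an
attribute sitting on the Worse axis has α = 0, one on the left edge has
α = 90. Since smaller α ranks better at equal distance, the must-be
default prefers attributes with strong dissatisfaction potential and
modest satisfaction potential — the defining trait of a must-be
quality. The defaults for the one-dimensional and indifferent POVs point
toward must-be because, for professional products, essential qualities
outrank merely attractive ones; both are configurable.

A wording note: descriptions of this method are sometimes phrased
against plots that invert the Worse axis (showing |Worse|), where
"preferring less pronounced Worse values" can read as the opposite of
what the formula does in the signed convention. This package works in
the signed convention throughout and treats axis inversion purely as a
plotting concern; the formula's behaviour is validated cell-by-cell
against the published distance/angle/coefficient tables it reproduces.

### Numerical choices

* **Full precision internally, rounding at the reporting boundary.**
  All indices, coordinates, distances and angles are carried at double
  precision; printed tables round with `round_half_up()` (ties away
  from zero, 2 decimals for indices and coefficients, integer degrees
  for angles). Published tables of this method often show
  one-unit-in-last-place artifacts because they chain *rounded*
  intermediates; recomputation at full precision reproduces every cell
  within one ULP and the rank permutations exactly, and the test suite
  asserts exactly that tolerance.
* **α at the corner itself is 0** (hence f = 0, always rank 1). The
  directional limit does not exist there; 0 is the unique choice that
  keeps "the corner is best".
* **Ties.** Argmax ties in the mode/if-then rules are broken by the
  fixed precedence M > P > A > I > R > Q — a conservative
  essentials-first ordering; the classical literature exhibits no tie
  and prescribes no rule, so this is a documented package choice
  (configurable via `precedence`). If-then equality (P+A+M = I+R+Q)
  falls back to the global argmax. Exact `f` ties keep input order and
  are flagged in a `tied` column rather than silently broken.
* **Degenerate inputs.** Better/Worse are undefined when A+P+M+I = 0
  (all answers R/Q): this is an error, not 0/0 → NaN. Attributes with
  zero records, empty rankings, fractions outside (0, 1) and
  out-of-square coordinates all raise domain errors naming the problem.
* **Relevance → importance.** The five relevance levels map to the
  uniform grid 1, 0.75, 0.5, 0.25, 0 (`kano_importance_map()`). The
  grid is a package default chosen because it spans the full [0, 1]
  scale with equal steps and yields importance magnitudes in the
  0.66–0.94 range typical of published panels; any alternative mapping
  can be supplied wherever an `importance_map` argument is accepted.
* **Split rounding.** `split_groups()` gives group A ⌈fraction · n⌉
  respondents — deterministic, and a 50% split of an even panel yields
  two equal halves (382 → 191 + 191).

## Group comparison

`compare_counts()` is the plain Pearson chi-square on an observed count
table — no continuity correction, no exact test — matching the standard
reporting convention for demographic homogeneity checks between
randomized groups. Small expected counts produce a warning but do not
change the statistic, and no multiple-testing adjustment is applied:
p-values across many characteristics are raw and should be read as
descriptive. `between_group_distance()` quantifies how far the same
attribute lands in two groups; below 0.05·√2 ≈ 0.0707 (5% of the
maximal distance) two placements are conventionally considered
equivalent.

## The synthetic generator

`generate_survey()` draws each respondent × attribute cell
independently: one (functional, dysfunctional) pair from the
attribute's 5 × 5 probability table (plus optional incomplete-pair
mass, with the missing half chosen at random) and one relevance level
from its 5-point distribution. `profile_from_counts()` inverts a count
vector into such a profile by placing each category's mass on one
canonical representative pair (A → (delighted, expected), P →
(delighted, dislike), M → (expected, dislike), I → (neutral, neutral),
R → (dislike, expected), Q → (delighted, delighted)) and splitting the
relevance mass between the two grid levels bracketing the target mean —
so the induced category distribution and expected importance match the
calibration target exactly in expectation.

What the generator emulates: marginal per-attribute category and
relevance distributions, missingness rates, respondent-level strata
frequencies, and (optionally, via `consistency`) a crude form of
within-respondent answer coupling. What it does not emulate: the full
5 × 5 cell distribution of real panels (only one representative cell
per category), correlations between attributes or between answers and
strata, ordered-scale response styles (acquiescence, extreme
responding), and nonresponse mechanisms beyond independent missing
mass. Passing tests on generated panels therefore demonstrate
correctness of the computational chain and sampling behaviour of the
estimators under the stated independence model — not robustness to the
richer dependence structure of real surveys.

### Sampling noise and rank stability

A full rank permutation is recovered from a finite panel only when
every pairwise gap in `f` exceeds the sampling noise. Better/Worse
proportions estimated from n respondents fluctuate with standard error
≈ √(p(1−p)/n), and the reference profiles bundled with the package
contain one adjacent pair (usability vs transparency) whose
full-precision f-gap is only ≈ 0.008 — comparable to that noise even at
n = 5000, where the test suite's Monte-Carlo accordingly recovers the
full nine-attribute reference permutation in roughly 85% of seeds
rather than near-certainly. This is a property of the reference data's
geometry, not of the implementation: the remaining eight ranks are
stable, and the package's rank-stability property test formalizes the
guarantee that perturbations below the Lipschitz radius of the minimal
f-gap can never change the permutation.

Test problem sizes, as package choices: convergence of the indices is
checked at n ∈ {100, 1000, 10000}; calibration envelopes at the
reference group size n = 191 (99% binomial envelopes); permutation
recovery at n = 5000 over 50 seeds.

## Limitations

* The 5 × 5 categorization matrix is fixed to the classical one;
  modified grids are out of scope.
* Importance weighting is scalar multiplication only.
* Question-order effects are not modelled: the data model does not
  record presentation order (randomized orders are the surveyor's
  concern and no analysis here uses them).
* Ranking quality inherits the survey's biases: self-selected panels
  with low response rates, or strata with few respondents, shift
  coordinates far more than the 0.0707 equivalence yardstick, as the
  bundled reference's interest-stratification illustrates.
```{r example}
ref <- app_quality_counts("A")
ind <- timko_indices(ref, importance = ref$importance)
rank_attributes(data.frame(attribute = ind$attribute,
                           worse = ind$worse_weighted,
                           better = ind$better_weighted))
```
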