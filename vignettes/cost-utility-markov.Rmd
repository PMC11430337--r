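---
title: "A Markov cohort cost-utility model for post-stroke functional recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for post-stroke functional recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The model

`strokecea` evaluates a two-arm comparison of post-stroke care strategies
with a six-state Markov cohort model on the modified Rankin Scale. The
states are mRS 0–1 (functional recovery; the two best grades are merged),
mRS 2, 3, 4 and 5, and death (mRS 6), which is absorbing. The model runs in
discrete 3-month cycles over a 2-year horizon — eight cycles — because
3 months is the shortest spacing with repeated observations on the
assessment schedule the model assumes (day 10/discharge, then months 1, 3,
6, 12, 18, 24), and 2 years is as far as the follow-up data reach; no
extrapolation beyond the horizon is attempted.

The cohort's state occupancy evolves as

$$\mathbf{o}_c = \mathbf{o}_{c-1} M_c, \qquad c = 1,\dots,8,$$

with $\mathbf{o}_0$ the state distribution at day 10/discharge and $M_c$ the
cycle-specific 6×6 row-stochastic transition matrix. Evaluation is at the
cohort (expected-value) level; a microsimulation of individual trajectories
exists in the package only as an independent check (`microsimulate()`),
whose occupancy fractions must agree with the cohort trace within binomial
sampling error.

### Assumptions

* **Markov property per cycle.** The next state depends only on the current
  state; there are no tunnel states and no covariate adjustment.
* **Death is absorbing** and its occupancy is therefore monotone.
* **Time-inhomogeneity by observation interval.** Each observation interval
  contributes its own matrix; the two model cycles inside one 6-month
  interval share a single matrix (a constant-hazard assumption within the
  interval).
* **No half-cycle correction** by default: a state occupied at the start of
  a cycle earns that cycle's full cost and utility. Setting
  `half_cycle_correction = TRUE` values each cycle at the mean of its start
  and end occupancy instead.

## From panel data to cycle matrices

`count_transitions()` tabulates, per arm and interval, how many patients
moved from state *i* at the interval's start to state *j* at its end;
patients missing either visit are excluded (and counted in the result).
`counts_to_probability()` row-normalises; a row with no observations gets
the identity row — the unobserved fraction is assumed to stay put, a
conservative and transparent policy that is warned about rather than
silently pooled.

Intervals already on the 3-month grid are used directly: the first-visit →
month-3 transition is the cycle-1 matrix (the day-10/discharge distribution
being the model's initial state), and month 3 → 6 is cycle 2. The month-1
assessment is unused by default; `use_month1 = TRUE` instead derives cycle 1
from the month-1 → month-3 transition rescaled through hazards, for users
who prefer not to stretch the ~2.7-month first interval onto the 3-month
grid. The 6-month intervals are re-timed through continuous-time hazards:

$$Q = \frac{\log P_{6\mathrm{m}}}{0.5\,\mathrm{yr}}, \qquad
  P_{3\mathrm{m}} = \exp(0.25\,Q),$$

using the principal matrix logarithm and exponential, so that
$P_{3\mathrm{m}}^2 = P_{6\mathrm{m}}$ exactly for embeddable inputs.

### Numerical choices

* The matrix exponential is `Matrix::expm()` (accurate to machine
  precision). The principal logarithm first tries the eigendecomposition
  route (`pracma::logm`), validates it by the exponential round trip
  (tolerance 1e-8), and falls back to an inverse-scaling-and-squaring
  implementation (repeated Denman–Beavers square roots, then a truncated
  Mercator series) when empirical matrices are defective — e.g. several
  identical identity rows make the eigenvector matrix singular.
* **Embeddability repair.** Empirical matrices are rarely exactly
  embeddable. Small negative off-diagonal entries of $Q$ are zeroed and the
  removed mass added to the diagonal, keeping row sums at zero; the total
  removed mass per matrix is recorded (`repair_norms`). This is the minimal
  perturbation that restores a valid generator.
* **Singular or negative spectra.** A sparse matrix (e.g. a one-patient row
  duplicating another row) can have a zero or negative real eigenvalue, so
  no principal logarithm exists at all. The matrix is then shrunk toward
  the identity, $(1-\varepsilon)P + \varepsilon I$, by the smallest
  $\varepsilon$ on a doubling ladder (1e-8 … 0.05) that restores
  embeddability; $\varepsilon$ is warned about and logged. Beyond 0.05 the
  operation aborts rather than distort the data further.
* Stochasticity is enforced at 1e-10 (row sums), round trips at 1e-8;
  entries are clamped to [0, 1] after exponentiation with renormalisation
  only when clamping moves a row sum by less than 1e-9, else an error.

## Valuation

Costs enter as annual per-state direct costs in the source currency and
price year (the structure follows registry-style Swedish stroke costing:
one figure for the grouped mRS 0–2 and one each for mRS 3, 4, 5, separately
for the first and second year after stroke). The grouped cost is split onto
the model's mRS 0–1 and mRS 2 states with weights (1/3, 2/3) by default —
the milder state is assumed to generate one third of the grouped cost —
and the weights are configurable because the split is an assumption, not
data. Death carries zero cost: costs incurred before dying are already
accrued in the living states. Costs are CPI-adjusted to 2022 and converted
to EUR; all internal arithmetic is in 2022 EUR, with USD mirrored at a
fixed 1.08 only at reporting time.

Utilities are EQ-5D-style per-mRS preference weights in [0, 1]; the merged
recovery state takes the mean of the mRS 0 and mRS 1 utilities, death has
utility zero.

Each cycle $c$ contributes, discounted at annual rate $r$ (default 3%) with
factor $(1+r)^{-0.25c}$:

* cost: start-of-cycle occupancy × the per-cycle state cost vector (annual
  cost / 4; year-1 costs for cycles 1–4, year-2 for cycles 5–8), plus an
  optional per-cycle treatment acquisition cost in the intervention arm
  (default 0, charged in cycle 1 — the 3-month course — when set);
* QALYs: start-of-cycle occupancy × the state utility vector.

Two QALY accumulation conventions are provided. The default, `per_cycle`,
credits the full state utility each cycle, i.e. reports utility-weighted
*cycle counts* (a fully healthy cohort accrues ≈ 8·u over the horizon); this
matches the reward convention of common decision-tree software and is the
scale on which this model family's results are usually printed. The
conventional year-scaled QALY is `per_year`, exactly 0.25 × the per-cycle
value. The identity is exact and tested; readers comparing against
life-year-scaled analyses should use `per_year`.

## Decision analysis

`compare_arms()` reports ΔC, ΔE, the ICER ΔC/ΔE (undefined at ΔE = 0), the
CE-plane quadrant and dominance. Quadrant II (cheaper, more effective)
means the intervention dominates; on the axes, the tie-break is "better or
equal on both, strictly better on one" → dominant, which matches the
sign-enumeration oracle in the tests.

**One-way DSA** (`one_way_dsa()`) varies each scalar economic input to its
low/high bound (±20% of base by default, utilities and split weights capped
at 1 — the bounds are conventional, since no interval information
accompanies point estimates), re-runs the valuation, and ranks parameters by
the absolute swing of the outcome (ICER by default; incremental net
monetary benefit at a reference WTP is available because the ICER's sign is
not comparable across quadrants — rows whose two bounds land in different
quadrants are flagged). Transition probabilities are not varied one-way:
a single row cannot move without its complement, so their uncertainty is
handled jointly in the PSA.

**PSA** (`psa()`, `psa_sampler()`) draws all parameters jointly:

* utilities ~ Beta, moment-matched to the base value with coefficient of
  variation 0.1 (variance truncated to the feasible Beta range);
* costs ~ Gamma, moment-matched with coefficient of variation 0.2;
* transition rows ~ Dirichlet, placed directly on the model's per-cycle
  rows with concentration $n_i \hat p_{ij}$, where $n_i$ is the number of
  patients observed at risk in state $i$ at the start of the cycle's source
  interval (0.5 replaces zero cells). The two cycles sharing one 6-month
  interval share one draw, preserving the equal-cycles assumption.

The Dirichlet sits on the cycle matrices rather than on the 6-month
interval matrices because re-running the logarithm on sampled matrices
generates spurious embeddability failures: a noticeable fraction of sparse
subgroup draws has a negative or zero eigenvalue, which is an artifact of
the sampling route, not a statement about the data. Parameterising the
rows the model actually consumes keeps every draw simplex-valid with the
correct information content. The default CVs are conventions; both are
configurable.

One master seed drives a PSA run; per-draw substreams are derived from it,
so results are reproducible bit-for-bit and independent of evaluation
order. A draw whose evaluation fails is kept as a `quadrant = "error"` row
with missing increments (never silently dropped) and counts as *not*
cost-effective in the CEAC. The CEAC uses the strict inequality
$\mathrm{WTP}\cdot\Delta E - \Delta C > 0$; ties count against the
intervention. The default WTP grid is €0–100,000 in €1,000 steps.

## The synthetic trial generator

`generative_spec()`/`generate_cohort()` simulate two-arm mRS panels: per
arm, an initial distribution at the first visit and one transition matrix
per inter-visit interval; trajectories are sampled from that inhomogeneous
chain, so death is absorbing by construction. Missingness, when enabled, is
missing-completely-at-random per visit, never at the first visit, default
0 — panel completeness is the estimation default, and dropout mechanisms
are out of scope.

The reference scenario (`synthetic_trial_spec()`) fixes the study
conditions for the examples, tests and the acceptance script: 287
intervention and 261 comparator patients; a day-10 distribution
(0.02, 0.08, 0.28, 0.45, 0.17, 0) whose median is mRS 4 with lower quartile
3, typical of moderate-severity stroke at discharge; per-interval recovery
intensities that peak in months 1–6 and slow thereafter; quarterly
mortality around 1–2%, higher in worse states; and a 35% relative increase
in upward-movement probability in the intervention arm, reflecting a
therapy that accelerates recovery without directly altering mortality. The
economic stand-ins (`synthetic_econ_params()`) are of realistic magnitude
for high-income-country stroke care (annual year-1 costs from ≈ €11k for
recovered patients to ≈ €66k for mRS 5, after CPI 1.15 and SEK→EUR 0.095)
with a typical EQ-5D gradient (0.95 down to 0.05). These values are the
package's own synthetic reference — chosen once for realism, not estimates
of any published cohort — so worked-example outputs characterise the
method, not any actual therapy.

What the generator deliberately does *not* emulate: visit-time jitter,
informative dropout, covariate-driven heterogeneity within arm,
measurement error in mRS grading, and any treatment mechanism beyond the
arm-specific matrices. Passing tests therefore demonstrate that the
estimation-to-decision chain is correct under the model's own assumptions;
they cannot certify behaviour under misspecification of those assumptions
on real data.

## Problem sizes in the test surface

Parameter-recovery checks use n = 2,000 per arm, where binomial standard
errors are small enough to detect systematic bias while the whole suite
runs in about a minute; the cohort-vs-microsimulation check uses 200,000
individuals; PSA checks use 2,000 iterations (the full 10,000 changes the
acceptability fractions by well under a percentage point in quadrant-II
scenarios). Statistical assertions require ≥95% of entries within three
binomial standard errors, matching the multiplicity of entry-wise
comparisons.

## Known limitations

* Transition estimation is frequency-based with hazard re-timing; no
  continuous-time multistate likelihood (and hence no use of partially
  observed intervals beyond the complete-pair counts).
* Subgroup analyses re-estimate transitions on filtered panels and share
  the economic inputs; small subgroups inherit sparse-row policies
  (identity rows, shrinkage) whose footprint is logged but still a
  modelling choice.
* The 2-year horizon truncates lifetime consequences; a dominant result
  over 2 years need not be dominant over a lifetime.
* Costs and utilities are external to the trial design the generator
  mimics; transporting them across health systems is the user's
  responsibility.
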