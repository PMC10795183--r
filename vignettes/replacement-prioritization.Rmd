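---
title: "Replacement prioritization for large medical equipment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replacement prioritization for large medical equipment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medequip)
```

## Problem and scope

Deciding which capital imaging device to replace first is a
multi-criteria decision problem: workload, patient service, technical
condition and economics pull in different directions, and the raw
numbers live on incomparable scales. `medequip` implements one complete
chain for this decision — indicator construction from operational logs,
combined subjective/objective weighting, and a GRA-TOPSIS fusion
ranking with comparator methods — for fleets of at least two devices
scored on at least two indicators. Data acquisition (IoT collectors,
PACS/HIS interfaces) and the expert process that selects the indicator
set are out of scope: the package starts from logs, profiles and score
panels already in hand.

## The indicator system

Nine indicators in four groups (operational security, social benefit,
technical condition, economic benefit); see `default_indicators()`.
Conventions the formulas depend on:

* All durations are minutes; timestamps are ISO-8601, parsed to UTC.
  The per-exam preparation allowance added to the mean exam duration is
  2 minutes by default (`prep_minutes`), the rated working time is
  480 min per day, and the reference useful life is 6 years. These are
  the conventional values for hospital imaging fleets and are all
  overridable per profile.
* Operating saturation and work intensity read the workload as
  `(τ + prep) · N`: the preparation time is a per-exam add-on to the
  mean duration, so saturation can exceed 1 when turn-around eats into
  powered-on time.
* The mean patient wait averages `exam_start − scheduled_time` over the
  records that carry an appointment, clamping each wait at zero — an
  exam that started early is a zero wait, not a negative one. Records
  without an appointment are excluded from the denominator. Booked
  appointments and completed exams are therefore allowed to differ.
* The mean inter-exam interval averages the `m − 1` consecutive gaps
  `start_i − end_{i−1}` after sorting by start time; overlapping
  records clamp to a zero gap.
* Payback (X42) is undefined when revenue equals cost (hard error) and
  infinite when revenue falls short. Because X42 is a cost-direction
  column, an infinite payback must still sort as "delay replacement";
  `build_decision_matrix()` replaces it by the largest finite payback
  in the cohort times 10 (configurable), which preserves the monotone
  reading without poisoning the min-max normalization with `Inf`.

Directions: X11–X32 benefit, X41–X42 cost, following the indicator
system's property column. Direction-adjusted normalization maps every
column so that larger normalized values mean better performance; the
replacement reading ("worse performer → replace sooner") is handled
entirely by the fusion orientation, never by flipping individual
columns ad hoc.

## COWA expert weighting

For each indicator the `n` expert scores are sorted descending and
combined with binomial position weights
`θ_{j+1} = C(n−1, j)/2^{n−1}`. The weights are symmetric and
concentrated in the middle, so the most extreme opinions at either end
contribute least — replacing the top score by a less extreme one moves
the aggregate by at most `θ₁·Δ`. The aggregate is a convex combination
of the scores (so it stays in `[min, max]`), and normalizing the nine
aggregates gives the subjective weight vector. Ties in the sort carry
equal values, so no tie rule is needed; a stable sort keeps the exposed
contribution vector reproducible. Scores are accepted as reals in
`[0, 10]`; no rounding is applied.

## PCA objective weighting

The decision matrix is normalized (direction-aware min-max by default;
z-score is exposed as an alternative since correlation-based PCA is
scale-free under either), the Pearson correlation matrix of the
indicator columns is eigendecomposed, and components are retained by
policy:

* `cumulative` (default, threshold 0.85): smallest p reaching the
  threshold. On the reference case this retains four components at
  86.4 % cumulative variance; the Kaiser rule would drop the fourth
  (eigenvalue 0.924), which is why cumulative is the default.
* `kaiser` and `fixed` are available.

The printed loading tables in this literature do not state how loadings
become indicator weights. The package uses
`score_i = Σ_{j≤p} a_j·|c_ij| / Σ_{j≤p} a_j` — each indicator's
absolute loadings averaged under the variance shares of the retained
components, renormalized by the cumulative variance — and normalizes
scores into weights. On the embedded reference loading table this
reproduces every printed score and weight cell to within one unit in
the third decimal (the residual is the 3-decimal rounding of the
printed loadings themselves), which is the evidence for adopting it.
Absolute values are taken because eigenvectors are sign-indeterminate;
weights are invariant to flipping any component.

A constant indicator column carries no ranking information; min-max
normalization maps it to 0.5 with a warning and it enters the
correlation step as an uncorrelated column rather than aborting the
run.

## Game-theoretic combination

With `W₁` (COWA) and `W₂` (PCA), the combination coefficients solve the
pairwise-dot-product system `[Wⱼ·Wₖ] λ = [Wⱼ·Wⱼ]` — the standard
first-order system of the combination-weighting compromise. (The
variant sometimes printed with `W₁W₂ᵀ` on the right-hand side does not
follow from differentiating the objective and reduces to the correct
system only when the inputs coincide; the standard form is
implemented.) `λ` is normalized to sum to 1 and `W* = Σ λ*_k W_k`.

Two numerical guards keep `W*` a usable weight vector: a singular
system (near-identical inputs) falls back to equal coefficients, and
negative normalized coefficients — which arise legitimately when one
vector sits "between" the others — are clipped to zero and
renormalized, with warnings in both cases. Clipping keeps `W*` a convex
combination, so non-negativity of the weights survives; the compromise
objective at the clipped solution never exceeds the objective at either
input alone.

## GRA-TOPSIS fusion ranking

On `S = (w_j z_ij)`: the positive/negative ideal rows are the column
maxima/minima (best/worst-performing profiles), `d±` are Euclidean
distances to them, and the gray relational coefficient of entry `ij`
against an ideal is `(Δmin + ρΔmax)/(Δ_ij + ρΔmax)` with the global
extremes of the respective deviation matrix and resolution factor
ρ = 0.5 (the conventional value; smaller ρ sharpens contrast). Gray
degrees aggregate rows under the indicator weights; the `1/n`
prefactor sometimes attached to that mean is dropped because the
subsequent own-maximum normalization cancels any constant factor. The
weights thus enter twice (inside `S` and in the degree), which is
retained as the method's printed form; `gray_degree_weighting =
"uniform"` exposes the single-weighting alternative. All four measures
are divided by their own maxima and fused:

* `orientation = "priority"` (default): `T⁺ = α₁D⁺ + α₂L⁻`,
  `T⁻ = α₁D⁻ + α₂L⁺`, `ξ = T⁺/(T⁺+T⁻)`; larger ξ = replace sooner.
  This assignment reproduces the reference case's decision column
  exactly (0.568 / 0.433 / 0.380 / 0.424), which is why it is the
  default.
* `orientation = "proximity"`: the transposed assignment (closeness to
  the healthy ideal scores high). The two are complementary,
  `ξ_priority + ξ_proximity = 1`.

α₁ = α₂ = 0.5 by default (equal taste for position and shape
information); they must be strictly inside (0, 1) and sum to 1.

Degenerate inputs: identical rows make every gray coefficient 1 (with
a warning) and zero total distance is a hard error in TOPSIS; a zero
maximum in any of the four measures aborts normalization with the
measure named.

### Comparators

* Plain TOPSIS: `d⁺/(d⁺+d⁻)` — the worst performer scores highest
  (priority orientation).
* Plain GRA: weighted gray degree to the worst-performing (replacement
  reference) row.
* VIKOR: standard S/R/Q with v = 0.5 on the direction-adjusted values,
  oriented so the most replacement-worthy profile is VIKOR's "best"
  (Q = 0 → replace first). The published per-method score columns for
  the comparators are not derivable from the published mid-pipeline
  measures, so the comparators are validated against hand-computed
  examples and structural properties (dominance recovery, tie
  averaging) rather than against printed comparator scores.

Ranks are always 1 = replace first with average-rank tie handling.

## Concordance

`kendall_w()` follows the "k related samples" convention: each device
(block) ranks the methods' scores, `W = 12S/(n²(k³−k))`,
`χ² = n(k−1)W`, p from the upper χ² tail with `k − 1` df. This
orientation reproduces the reference concordance table (W = 0.812,
χ² = 6.5, p = 0.039); the transposed orientation (methods ranking
devices) is exposed via `transpose = TRUE` but on score columns it is
degenerate whenever all methods order the devices identically (W = 1).
Ties are average-ranked; the tie-correction term in the denominator is
off by default (the reference data has no ties) and available via
`tie_correction = TRUE`. The p-value is reported for a single test;
no multiplicity handling is needed or applied.

## Synthetic cohorts

`generate_cohort()` inverts the indicator formulas: the exam count
comes from the work-intensity target and the rated time (rounded to an
integer), powered-on time from the saturation target, working time
from utilization, age from the life index, and financials from the
cost-benefit and payback targets under a constant revenue per exam
(600 per exam by default — the simplest model consistent with period
totals). Exams are laid out sequentially from 08:00 of day one with
the requested mean gap, and appointments precede starts by the
requested mean wait; truncated-normal noise (s.d. parameters in
`cohort_spec()`, zero by default) perturbs durations, gaps and waits.
The generator returns the *realized* indicator values as ground truth
— the requested targets adjusted for integer exam counts and noise —
so the round trip through `build_decision_matrix()` is exact to 1e-9
at any noise level, and exact against the requested targets at zero
noise. Feasibility is checked up front (schedule must fit the horizon;
devices must be cost-recovering, X41 > 1, so payback is finite).

What the generator does *not* emulate: day boundaries and shift
patterns, case-mix-dependent durations, correlated failures, or
revenue heterogeneity. Passing tests on synthetic cohorts therefore
demonstrate the algebra and the pipeline plumbing, not robustness to
the messiness of real HIS extracts.

`generate_expert_panel()` draws scores around per-indicator anchors
with s.d. `2·(1 − consensus)` points, clipped to `[0, 10]`; at full
consensus the panel equals the anchors, making COWA weights
proportional to them. Both generators are pure functions of
`(spec, seed)`.

## Problem sizes and runtime

Everything is closed-form linear algebra on `m × 9` matrices; the
bundled test suite runs cohorts of 4–8 devices, expert panels of 8,
and a 1000-row simulation for the correlation null check, completing
in a few seconds on one core. The pipeline scales linearly in devices
and indicators; fleets of hundreds of devices remain sub-second.

## Known limitations

* The PCA score reconstruction is a documented convention, not a
  published formula; alternative loadings-to-weights rules exist.
* With four devices the indicator correlation matrix has rank ≤ 3;
  PCA weighting on such small fleets leans heavily on the retention
  policy, and the embedded reference loading table is the safer
  validation anchor.
* Plain-GRA and plain-TOPSIS comparator scores are standard-definition
  implementations; printed comparator columns from other toolchains
  may differ by their internal normalization choices even when the
  rank order agrees.
* The game combination uses only pairwise dot products; no richer
  bargaining structure is modeled.
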