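---
title: "Mokken scale analysis with mokkenscale: models, defaults and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mokken scale analysis with mokkenscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mokkenscale)
```

## The model

Mokken scale analysis evaluates whether a set of k questionnaire items,
scored 0..m, behaves as a probabilistic cumulative scale for a single
latent trait θ. The **monotone homogeneity model (MHM)** assumes:

1. *Unidimensionality* — one θ underlies all items;
2. *Local independence* — responses are independent given θ;
3. *Monotonicity* — each item step response function (ISRF),
   P(X_i ≥ s | θ), is non-decreasing in θ (for a binary item this is the
   item characteristic curve, ICC).

Under the MHM the total score orders respondents stochastically on θ,
which is what licenses sum scoring. The **double monotonicity model
(DMM)** adds *non-intersection* of the response functions across items.
For binary items non-intersection is equivalent to an **invariant item
ordering (IIO)**: the items keep one difficulty order at every trait
level, so item-level comparisons (e.g. symptom hierarchies) are meaningful
for every respondent. Curves may touch or coincide; they may not cross.

None of this fixes a parametric curve shape — that is the point. The price
is that model evaluation rests on manifest diagnostics rather than
likelihood fit statistics, and this package implements that diagnostic
toolkit.

### Scalability coefficients

For an item pair, H_ij divides the observed covariance by the maximum
covariance attainable under the observed marginals; item (H_i) and scale
(H) coefficients are ratios of the corresponding sums, not means of
ratios, so H always lies between the smallest and largest H_i. The
maximum is reached by the comonotonic (Guttman-ordered) coupling: sort
both marginal score distributions and pair them off rank by rank — the
Fréchet upper bound. `coef_h()` uses the population divisor N in both
numerator and denominator (only the ratio matters; one convention keeps
the bound exact), and both E[XY] terms are accumulated with identical
arithmetic so that error-free cumulative data yields H_ij = 1 *exactly*,
not merely to rounding.

Deterministic Guttman data gives H = 1; independent items give H = 0 in
population. Interpretation bands (0.3 / 0.4 / 0.5 for unscalable / weak /
medium / strong) follow the field's rules of thumb, as do the H^T bands
for item-ordering accuracy (below 0.3 too inaccurate to use, 0.3–0.4
somewhat low, 0.4–0.5 medium, above 0.5 sufficient).

Zero-variance items are an *error*, never silently dropped: a constant
item has Covmax = 0, its scalability is undefined, and silently removing
it would hide a data problem the analyst should see.

### H^T — the transposed coefficient

`coef_ht()` computes H with respondents and items exchanged: instead of
asking how well items order persons, it asks how consistently persons
order the items. Respondents with constant response patterns contribute
zero to both the covariance and maximum-covariance sums and therefore
drop out of the ratio; the coefficient is undefined only when *every*
pair of respondents is constant or identical. The implementation
aggregates identical response patterns and works on pattern×pattern
matrices, so cost scales with the number of distinct patterns rather
than N².

## Automated item selection (aisp)

`aisp()` implements the classical bottom-up search. A scale is seeded by
the best admissible pair — largest H_ij among pairs whose positivity is
statistically supported and that reach the lower bound c — and grown
greedily by the admissible item that maximises the scale's H. Admissible
means (a) significantly positive H_ij with every member, and (b) after
the tentative addition *every* member's within-scale H_i ≥ c. Condition
(b) is deliberately stronger than vetting the candidate alone: an
incoming item can drag an existing member below the bound, and the
stronger condition guarantees that every reported scale passes a post-hoc
`coef_h()` audit at the bound. Ties on scale H go to the candidate with
the larger total maximum covariance with the selected items, then to pool
order, so the search is deterministic.

The positivity screen (`test_hij_positive()`) uses the large-sample
normal approximation for the item-pair correlation, z = r√(N−1),
one-sided — since Covmax > 0 for non-constant items, H_ij > 0 is
equivalent to a positive covariance. The test is isolated behind one
function and documented as replaceable (a permutation test is the obvious
alternative); no multiplicity correction is applied, matching the
descriptive use of the counts. `cutoff_sweep()` reruns the search on an
ascending grid of bounds (the conventional exploration raises c from 0.3
in steps of 0.05) to show how the pool fragments as homogeneity demands
rise. A genetic-search variant is out of scope; unknown `strategy` tokens
fall back to the bottom-up search with a warning.

## Monotonicity diagnostics

Manifest monotonicity replaces the unobservable θ with the **restscore**
— the total over all items except the focal one. Respondents are grouped
by restscore; within each group, each item step's endorsement proportion
is estimated; and for every ordered group pair r < s the proportions are
compared. Under monotone ISRFs the proportion should not fall. A decrease
of at least `minvi` counts as a violation (#vi); each violation gets a
one-sided pooled two-proportion z-test (#zsig counts the significant
ones); #ac counts all active comparisons, R(R−1)/2 per item step for R
groups.

Tunables, with defaults and rationale:

* **minsize** (minimum restscore-group size): adjacent restscore values
  are merged, lowest first, until every group reaches this size — too-small
  groups make proportion estimates unstable, too-large a minimum leaves too
  few groups to see anything. The default follows the conventional
  sample-size rule: N/10 for N > 500, N/5 for 250 < N ≤ 500, N/3 (at
  least 50) otherwise, truncated. An undersized final group merges into
  its left neighbour; merging from the low end and resolving the remainder
  leftward makes grouping deterministic.
* **minvi** (minimum decrease counted, default 0.03): absorbs sampling
  wiggle; #vi is non-increasing in minvi by construction. Equal
  proportions are never violations, even at minvi = 0.
* **alpha** (default 0.05): per-comparison level of the z-tests, no
  multiplicity correction — #zsig is a descriptive count, not a family-wise
  decision.

The **crit** composite follows the MSP software tradition,

crit = 50(0.3 − H_i) + √#vi + 100·#vi/#ac + 100·maxvi + 10·√sumvi
 + 1000·sumvi/#ac + 5·zmax + 10·√zsum + 100·zsum/#ac,

set to 0 when #vi = 0. Its exact form is not canonical — the "< 40 means
no serious violation" screening convention is the only anchor — so all
components (maxvi, sumvi, zmax, zsum) are returned alongside it and users
can apply their own rule. `monotonicity_plotdata()` / `autoplot()` export
the group-level series (label, size, proportion) behind the diagnostic so
the curves can be redrawn and violations located visually.

## Invariant item ordering

`check_iio()` implements the manifest IIO (MIIO) check. Items are ordered
by overall mean; for each pair the restscore now excludes *both* members —
conditioning on a score that contains the compared items would tie the
comparison to itself mechanically. Within each restscore group, if the
overall order says item a is harder than item b but the group's
conditional means reverse that order by at least `minvi` per item step, a
violation is recorded *for both items*, and the reversal is tested with a
one-sided **paired** t-test on the within-group score differences. The
paired form is the deliberate choice here: both items are answered by the
same respondents, so the difference scores are the natural test variable,
and ignoring that pairing would waste the within-person correlation. A
deterministic reversal (zero variance of the differences) is significant
by convention. Pairs with tied overall means are skipped entirely — with
no expected order there is nothing to violate, and coincident response
functions are explicitly permitted by the model.

`backward_select_iio()` removes items one at a time — the item with the
most significant violations, ties broken by the lowest within-set H_i —
re-running the check after each removal, because violation counts depend
on the current item set. It stops when no significant violations remain
or only three items are left (with a warning), reports the step-by-step
trace (violation counts per item per step, NA once removed), and computes
H^T of the surviving set. The per-iteration H^T is skipped
(`compute_ht = FALSE`) since only the final set's ordering accuracy is
interpreted. `check_nonintersection()` is the binary specialisation — for
dichotomous items non-intersection and IIO coincide — and refuses
polytomous input with a pointer to MIIO.

## Molenaar–Sijtsma reliability

`ms_rho()` estimates total-score reliability as the correlation between
two hypothetical parallel administrations: the probability of giving the
same responses twice. Writing Y_a for the item-step indicators and
π_ab = E[P_a(θ)P_b(θ)] for the joint-positive proportions of a parallel
pair, the reliability is Σ_ab (π*_ab − p_a p_b) / Var(X₊), where π*_ab
is observable whenever a and b belong to different items. The within-item
entries — including the diagonal — are not observable and must be
reconstructed; non-intersection justifies reconstructing them from
popularity-ordered neighbours, which is why the DMM diagnostics should
pass before the estimate is interpreted (the result carries a note to
that effect).

The reconstruction, isolated in one internal function
(`interpolate_joint`), uses three elementary rules. With A / B the
nearest steps of *other* items more popular than a / less popular than b:

* interior: π̂_ab = π_Ab · π_aB / π_AB (multiplicative);
* most-popular extreme (no A): π̂_ab = π_aB · p_b / p_B;
* least-popular extreme (no B): the same ratio rule applied to the
  complementary (negative) responses.

Each rule is exact in the two regimes that bracket the model class —
deterministic Guttman data (ρ = 1 exactly) and independent items (the
diagonal collapses to p², ρ = 0) — and each is then refined by
first-order Richardson extrapolation against the same rule evaluated at
the next-farther neighbours, which cancels the leading smoothness bias
under double monotonicity. Development-time population calculations
(exact numerical integration over θ) put the residual bias of the
resulting estimator below 0.01 for equal-discrimination logistic banks
with discriminations in the 1–2.5 range, against roughly 0.02–0.05 for
the unextrapolated rules. Estimates are clipped to the feasible band
[p_a p_b, min(p_a, p_b)] (non-negative association is implied by the
MHM), and ρ is reported within [0, 1]. Item steps with degenerate
marginals (p = 0 or 1) carry no variance and are excluded; at least three
items must retain non-degenerate steps. Cronbach's alpha is reported
alongside; under the model it is the familiar lower bound and in
simulation sits visibly below the parallel-replication reliability, while
ρ tracks it closely.

Polytomous items are handled throughout by their step indicators — the
same ISRF treatment as the monotonicity check — with all within-item step
pairs reconstructed by the same rules.

## The synthetic-data generator

`item_bank()` describes items by response-function kind over a standard
normal trait (the IRT convention; nothing in the methods requires it, and
`sim_responses()` accepts any θ vector):

* `logistic` — graded-response-style cumulative steps
  P(X ≥ s | θ) = plogis(a(θ − b_s)) with ordered thresholds: monotone by
  construction, and equal-discrimination banks are non-intersecting, so
  they satisfy the DMM and exhibit IIO;
* `step` — deterministic Guttman steps (1(θ ≥ b_s));
* `unimodal` — a rise-then-fall binary curve, the canonical monotonicity
  violation;
* `table` — constant step probabilities: no trait dependence, hence
  independent items and zero scalability in population.

`sim_guttman()` builds error-free triangular-pattern data directly.
`inject_crossing_pair()` turns two binary logistic items into a crossing
pair (same location, different slopes, both at probability ½ at the
chosen crossing point) — the canonical IIO violation; crossings placed
beyond ±3 SD trigger a low-power warning since almost no respondents sit
past them. Responses are drawn with a single uniform per item-respondent
against the cumulative step probabilities, so local independence holds by
construction and the seed fully determines the output.
`population_h()` and `population_reliability()` integrate the bank's
curves over θ (trapezoid grid on ±8, step 0.005) to give the population
quantities that sample statistics converge to — the test suite checks
that convergence explicitly.

What the generator does *not* emulate: differential item functioning
across groups, missing-data mechanisms (the package's only missing-data
treatment is listwise deletion), correlated multi-trait structures beyond
independent blocks, non-normal trait distributions (unless supplied), or
response styles. Passing tests on generated data therefore demonstrates
that the *procedures* behave as the theory predicts under controlled
violations — not that any particular real instrument satisfies the model.

## Problem sizes and test design

The test suite validates each procedure at sizes where its statistical
guarantees are sharp but runs stay comfortable: exhaustive-enumeration
oracle agreement for `coef_h()` on 500 random instances with k ≤ 4,
scores ≤ 2 and N ≤ 12 (the oracle maximises covariance by enumerating
every contingency table with the observed margins); boundedness of all
coefficients across 200 simulated MHM datasets (k = 6, N = 2000);
null-behaviour of H at N = 100 000; detection of planted unimodal items
and recovery of planted two-scale structures in ≥ 90% of 15–20 seeds at
N = 2000; planted-crossing-item recall of backward selection on a
14-item, five-category bank at N = 4000 over 8 seeds; and reliability
calibration over 200 replications (k = 6, N = 2000) against the
parallel-replication oracle (regenerate responses twice from the same θ
draws and correlate total scores). The canonical well-behaved bank used
throughout is six equal-discrimination (a = 2) binary logistic items with
locations spread evenly on [−1.5, 1.5] — a strong scale of realistic
difficulty spread; flat (a = 0.6) items planted among steep (a = 2.2)
ones serve as crossing violators because a flat curve crosses nearly
every steep one inside the trait bulk.

## Numerical and interface choices

* Scores are validated as non-negative integers; inputs coded 1..m+1 are
  shifted to 0..m per item (recorded in an attribute). Every statistic in
  the package depends on scores only through differences and means, so
  the shift is observationally neutral; shifting is only triggered when an
  item's minimum observed score exceeds 0.
* Listwise deletion (`drop_incomplete()`) is the single supported
  missing-data treatment — all formulas assume a complete rectangle — and
  analysis functions refuse incomplete input rather than guessing.
* File I/O is strict: any non-integer, non-missing cell is an error naming
  the row and column; duplicate header labels are errors; round-trips
  through `write_item_data()` preserve values and missingness exactly.
* `restscore_groups()` merges ascending; `aisp()` and
  `backward_select_iio()` break ties deterministically (documented above),
  so every procedure is reproducible bit for bit.
* The workflow wrapper `run_scale_analysis()` is a pure composition of the
  exported step functions — running steps individually with the same
  settings reproduces its numbers exactly — and labels any step failure
  with the step name.

## Known limitations

Standard errors and confidence intervals for H are not provided. The
MSCPM and IT variants of the IIO check are not implemented, nor is a
genetic search for `aisp`. The crit composite is one defensible choice
among several; treat its absolute value as a screen, not a statistic with
known distribution. The positivity test and the per-violation z- and
t-tests are asymptotic and uncorrected for multiplicity; at very small N
the counts should be read descriptively (the pair-test table flags
N < 30). Local-independence testing is out of scope entirely.
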