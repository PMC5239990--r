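---
title: "Methods: ReliefF + rough-set feature selection with boosted trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ReliefF + rough-set feature selection with boosted trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfrs)
```

## The problem and the model

Clinical diagnosis tables — a few hundred labeled cases, a dozen mixed-type
condition attributes, a binary outcome — typically carry both *irrelevant*
attributes (no association with the diagnosis) and *redundant* ones
(informationally equivalent to others). The two defects call for different
tools: distance-based feature weighting (ReliefF) is good at scoring
relevance but blind to redundancy, while rough-set reduction removes
redundancy exactly but is expensive and has no notion of graded relevance.
This package chains them: ReliefF first prunes irrelevant attributes and
supplies a ranking; the rough-set reduct search then removes redundancy,
using the ranking as a search heuristic.

A decision table is an information system $S = (U, A = C \cup D, V, F)$.
For an attribute subset $P \subseteq C$, objects with identical value
tuples on $P$ are *indiscernible*; the equivalence classes of this relation
partition $U$. For a target set $X \subseteq U$, the lower approximation is
the union of classes wholly inside $X$, the upper approximation the union
of classes meeting $X$. The *positive region* $pos_P(D)$ is the union of the
lower approximations of the decision classes: the objects classifiable with
certainty from $P$. The *dependency degree*

$$\gamma_P(D) = \frac{|pos_P(D)|}{|U|} \in [0, 1]$$

measures how completely $P$ determines $D$; a *reduct* is a minimal $P$
with $\gamma_P(D) = \gamma_C(D)$, and an attribute's *significance* within
$P$ is the dependency drop its removal causes. All counts are integer-exact,
so reduct acceptance tests equality of counts, never float closeness.

## Pipeline stages and their tunables

**Equal-interval discretization** (`discretize_table()`, default
`n_bins = 4`). Rough-set machinery needs categorical data, so real
attributes are binned on their observed range with cut points
$m + i(M-m)/n$. Four bins keep the equivalence classes populated at the
target data scale (hundreds of objects); the count is exposed in
`rfrs_config(n_bins = )`. Assignment is right-closed (a value equal to a cut
point falls in the lower bin) and out-of-range values — possible when a
spec fitted on training data is applied to a test fold — clip to the outer
bins. Low-cardinality counts typed `ordered` (e.g. a 0–3 vessel count) are
deliberately exempt from binning: collapsing a 4-level count is lossy.

**ReliefF weighting** (`relieff_weights()`, defaults `k_neighbors = 10`,
threshold `delta = 0.02`). The per-attribute dissimilarity `diff` is 0/1 for
categorical attributes and range-scaled absolute difference for real ones.
Missing values are treated probabilistically via class-conditional relative
frequencies: with one value unknown, `diff` is one minus the probability of
the observed value given the unknown instance's class; with both unknown, it
is one minus the sum over the domain of the product of the two
class-conditional probabilities. Every instance serves as an anchor by
default (the classic random subsampling is available through `n_samples` +
`seed`), which makes the estimate deterministic; neighbours tied in
Manhattan distance at the $k$-th rank contribute fractionally, so the
weights are invariant under row reordering. Miss contributions are weighted
by class priors, $P(c)/(1 - P(\text{class}(anchor)))$, the standard
multi-class formulation. Selection keeps attributes with weight strictly
above δ.

**GA reduct search** (`ga_reduct_search()`). Chromosomes are inclusion
bitmasks over the condition attributes. The initial population is biased by
the min–max-normalized ReliefF weights, clipped to `[0.1, 0.9]` so no
attribute is ever certainly present or absent. Fitness is
$\gamma_P/\gamma_C - \lambda |P|/|C|$ with $\lambda = 0.1$, and
dependency-preserving individuals receive a +1 bonus so they strictly
dominate all non-preserving ones. Selection is tournament-of-2, crossover
uniform at rate 0.6, mutation bit-flip at 0.02, elitism 1, population 50,
generations 100 (all in `ga_params()`). The full mask is seeded into the
initial population, guaranteeing at least one reduct. Every preserving
individual met anywhere in the run is reduced to minimality by repeatedly
dropping the lowest-weight attribute whose removal keeps the dependency
intact — a deterministic, seed-independent tie-break — and the distinct
minimal subsets are superset-filtered and returned. Empty chromosomes are
repaired by activating the top-weight attribute; a table whose decision is
independent of all conditions ($\gamma_C = 0$) is rejected with an error.
The exhaustive enumerator `all_reducts_bruteforce()` (refused above 15
attributes, as reduct finding is NP-hard in general) provides the exact
reference: by partition-refinement monotonicity, drop-one minimality is
equivalent to subset minimality, so the GA's output on feasible tables is
always a subset of the brute-force reduct family.

**Boosted C4.5-style trees** (`train_tree()`, `boost()`). Trees split by
weighted gain ratio among attributes whose information gain is at least the
candidates' average (the C4.5 pre-filter); nominal attributes split multiway
and ordered/real attributes at the best midpoint threshold. Instances
missing a split value are excluded from that split's evaluation (gain scaled
by the known-weight fraction) and routed to the heaviest child at
prediction. Defaults: `min_leaf = 2` branch weight, unlimited depth, no
pruning — boosting prefers low-bias base learners; pessimistic
confidence-bound pruning (`cf = 0.25`) is available as an option. Boosting
is AdaBoost.M1 by *reweighting*, chosen over resampling for determinism
(resampling remains available behind `resample = TRUE`). A round with
weighted error exactly 0 gets a capped vote (10) and resets the weights; a
round with error ≥ 0.5 (the 0.5 boundary included) is discarded and the
weights reset; otherwise the vote is $\tfrac12\log((1-\epsilon)/\epsilon)$
and weights are renormalized. The ensemble score is the vote-weighted
average of ±1 tree votes, in $[-1, 1]$; zero scores tie to the positive
(disease-present) class, the convention used throughout the confusion-matrix
accounting.

**Evaluation** (`split_70_30()`, `jackknife()`, `roc()`). The headline
protocol is repeated stratified 70/30 splitting (default 10 repetitions)
reporting the *best* test accuracy, matching the convention of reporting the
highest performance over repeated runs; leave-one-out (jackknife) validation
is implemented alongside and selectable via
`rfrs_config(protocol = "jackknife")`. Metrics with an empty denominator are
reported as `NA`, never silently 0. The ROC sweep groups tied scores into a
single step and integrates by trapezoid, which equals the positive-negative
pairwise-comparison probability; percentages are rounded only at
presentation. Classification runs on the discretized reduct data, mirroring
the pipeline order in which discretization precedes everything downstream.

## The synthetic generators

`make_table()` plants known structure so every stage is testable without
external data: relevant attributes determine the class through a parity
rule; redundant attributes are value-permuted copies (hence
partition-identical — the strongest redundancy the rough-set machinery must
detect); noise attributes are class-independent. For every relevant
attribute a *witness pair* of objects — identical everywhere except on that
attribute and its copies, differing in class — is planted, so the
ground-truth minimal reducts are exactly the transversals choosing one
representative per duplicate group, for any noise level. `flip_noise`
perturbs the *rule* (each relevant-value tuple's class flips with that
probability, rejection-sampled so the rule stays non-constant and every
relevant attribute keeps a witness): labels remain a deterministic function
of the relevant attributes, keeping the table consistent. Per-row label
noise would instead put conflicting labels on identical tuples and collapse
the positive region to zero on the selected attributes — under exact
dependency preservation no reduct search can recover planted structure from
such data, which is a real limitation of rough-set reduction on noisy
tables, not of this implementation.

`make_statlog_like()` emulates the 13-attribute heart-disease schema:
real attributes are drawn from scaled Beta distributions moment-matched to
the published marginal means and standard deviations on the published
domains (moment matching keeps sample means unbiased, where a clipped normal
would shift them), categorical attributes from plausible level frequencies,
and the class from a logistic rule over the clinically informative
attributes, scaled so the rule's irreducible (Bayes) accuracy sits near
0.88 with ~43% disease prevalence — comparable to what published classifiers
achieve on the real data. Only marginals and kinds are emulated; the real
data's joint dependence structure (e.g. correlated ST measurements) is not.
Tests passing on these tables therefore demonstrate correctness of the
algorithms and sane end-to-end behaviour, not clinical performance on real
heart-disease data.

## Numerical choices and degenerate inputs

- Dependency uses exact integer counting (group hashing by mixed-radix
  integer keys, falling back to string keys when the radix product
  approaches 2^52); reduct acceptance is exact count equality.
- Missing values are `NA` throughout, a category of their own in
  indiscernibility, and never allowed in the decision column.
- A constant real attribute yields a single-bin spec (no error); a
  single-class table is rejected by ReliefF; an all-weights-below-δ
  selection warns and returns an empty set, which the pipeline turns into
  an abort with a diagnostic.
- Leaf-label ties go to the class more prevalent in the full training set,
  then to the lexicographically lower label; threshold ties resolve to the
  lowest cut; all seeds funnel through a single seeded generator per call,
  so identical configurations re-run bit-identically from the run manifest.

## Problem sizes used in the checks

The bundled verification uses tables the exact oracles can handle: GA
containment against exhaustive enumeration on 100 seeded tables of up to 8
attributes and 40 objects; algebraic identities on 1000 random 6–11-object
tables; ReliefF relevance separation at n = 500 over 100 seeds; end-to-end
recovery at n = 600 with rule noise 0.05; and the default protocol on the
270-instance heart-schema stand-in, whose best-of-10 test accuracy is
expected within roughly [80, 93] given the generator's ≈88% irreducible
accuracy and 81-case test sets.

## Known limitations

- Exact dependency preservation makes reducts brittle under per-row label
  noise (see above); variable-precision rough sets would relax this but are
  out of scope.
- Equal-width binning is the only discretization; entropy- or
  frequency-based schemes are not provided.
- The GA is heuristic: it provably returns only true reducts, but may miss
  some members of the full reduct family on hard instances within a fixed
  budget.
- Reported best-of-repetitions accuracy is optimistically biased relative
  to a mean over splits; both the full run table and the jackknife protocol
  are available for unbiased reporting.
- Binning is fitted on the full dataset before feature selection (mirroring
  the pipeline's stage order); a strictly per-fold spec can be fitted with
  `fit_equal_interval()` on each training split when leakage-free
  estimation matters.
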