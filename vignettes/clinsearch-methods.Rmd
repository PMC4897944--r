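---
title: "clinsearch: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clinsearch: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`clinsearch` automates three stages of clinical predictive modeling:
temporal aggregation of repeatedly recorded attributes, joint selection of
learning algorithm / feature-selection technique / hyper-parameter values by
progressive sampling, and real-time projection of accuracy and expected
outcome. This vignette explains each model, its assumptions and tunable
parameters, the synthetic data the tests rely on, and the decisions taken
where the design was genuinely open.

## 1. Temporal aggregation

Clinical event data arrive in tall EAV form — one row per observation, the
entity being (patient id, timestamp). A predictive model needs one row per
prediction instance, so each repeatedly recorded attribute is collapsed over
a lookback window ending at the instance's *index date* by an *aggregation
operator*. The shipped catalog covers ten operator families (min/max/mean,
presence, duration of use, count, monotone value trend, most recent value,
(relative) change, fraction of values high/low/normal/equal, monotone
weekly/monthly/quarterly event-frequency trend, and medication
intensification read as a dose trend), partitioned into categories whose
members yield redundant information; selection returns exactly one winning
period × operator pair per (attribute, category), so joined features are
non-redundant across categories.

**Window convention.** Windows are half-open, `(index_date − period,
index_date]`: the index-date observation counts, the far boundary does not.
The convention is arbitrary but must be fixed; every operator and both
implementations (package and brute-force test oracle) share it.

**Empty windows.** Numeric-valued operators return `NA` (imputed inside
each training fold downstream); presence/count/duration/trend/flag
operators return 0, since "nothing observed" is genuine information for
them. Monotone operators require ≥ 2 observations and *strict*
monotonicity; `change` is last − first, `relative_change` is
(last − first)/|first| and undefined at first = 0. Frequency trends bin the
window backwards from its end into whole 7/30/91-day bins, drop the partial
oldest bin, and need ≥ 2 complete bins. Medication
intensified/de-intensified has no consensus operational definition; we read
it as a strict monotone trend in the numeric dose values and flag that as a
convention. "Medication switched" and "multiple therapies" are registered
in the catalog but deliberately unimplemented (no accepted definition);
constructing them raises an error rather than guessing silently.

**Period enumeration** starts at the knowledge base's shortest period and
grows exponentially (default ×2) or arithmetically; when the progression
overshoots, the longest period itself is appended so the upper bound is
always a candidate.

**Relevance score.** Candidates are scored by information gain in bits for
categorical targets, with numeric features discretized into 10
equal-frequency bins and missing values forming their own bin; for
continuous targets the regression analogue (variance reduction over the
same discretization) is used. Scoring runs on a seeded sample of
min(5000, n) instances, stratified for categorical targets; the winning
pairs are then computed on all instances. Ties break to the shorter period,
then catalog order — deterministic by construction.

## 2. Progressive model search

The search space is the cross product of algorithm, feature-selection
technique (evaluator × search method — the technique choice is itself a
hyper-parameter of the search), and per-algorithm hyper-parameters. The
shipped roster has seven families (decision tree, random forest, gradient
boosting, k-NN, regularized logistic/linear regression, naive Bayes, linear
SVM) delegating to rpart, randomForest, xgboost, class, glmnet and e1071;
six feature evaluators (pass-through, information gain, correlation,
variance, model-based importance, symmetric uncertainty) and two search
methods (top-k ranking; greedy forward selection implemented as
score-minus-redundancy-penalty rather than wrapper refits, to keep
per-trial cost bounded). Continuous-target searches restrict the roster to
the four families with regression adapters.

**Rounds.** A fixed, stratified test sample guides the whole search; a
further untouched holdout (default 20% of the test split) is carved out for
final reporting only, because the test sample steers elimination and
ensemble selection and is therefore optimistically biased. Training samples
are nested prefixes of one stratified permutation, starting at
`min(ceiling(pool/8), 500)` rows (floor 2 per class) and doubling to the
full pool. Round 1 tests each algorithm's default plus `n_random = 20`
random configurations, topping up every evaluator to `min_tests = 20`
trials before it may be judged. Later rounds fit one bagged-tree surrogate
per algorithm (random forest regression over the encoded configuration plus
a log2 sample-size feature; mean/variance across trees) and propose 10
local-search plus 10 pool candidates by expected improvement, interleaved;
with fewer than d + 2 trials the surrogate is undefined and proposals are
purely random. From round 3, 30 pool candidates are first screened on the
round-1 sample; the best 10 become the pool group and the other 20 enter
the surrogate's training set as scaled estimates (observed small-sample
quality plus the mean uplift seen between the two sizes, clipped to [0,1]) —
flagged `estimated` and excluded from potentials, the best-so-far curve and
the final report. The incumbent for EI is the algorithm's best quality at
the current sample size (falling back to its overall best): quality is not
comparable across sizes, and the size feature inside the surrogate carries
the rest.

**Elimination.** An algorithm's potential is its best completed quality;
after round r, survivors lie within δ·2^(1−r) of the leader (δ = 0.10 —
scale-free across AUC and R²), at least two survive until the final two
rounds, and only the arg-max enters the full-data round. One lowest-
potential evaluator is dropped per round, only after all have ≥ 20 counted
trials, until at most 4 remain; dropped evaluators leave all encodings.

**The full-data round** re-tests only the `final_round_trials = 4` best
distinct combinations rather than proposing new ones: the round exists to
pick *the* combination on the complete pool, and this keeps full-size
trainings (including the winner's refit) within a handful while an
exhaustive grid needs dozens.

**Runtime model.** A candidate's time is predicted as baseline (default
configuration at round-1 size) × (n/n₀)^p × hyper-parameter ratio; the
ratio uses either a log-time regression (A) or a product of declared
per-parameter ratio functions (B), whichever has the lower leave-one-out
absolute log-error for that algorithm, and is 1 before 5 trials exist.
Candidates predicted beyond f·T (f = 2, T starting at 10 and doubling per
round) are skipped up front. In the default deterministic mode the model
consumes an analytic cost (rows × per-algorithm exponent × declared
hyper-parameter factors) rather than wall-clock, so the skip set — and with
it the entire ledger — replays bit-identically; wall-clock timing mode is
available behind `deterministic = FALSE` and is inherently nondeterministic.
Per-trial RNG seeds derive only from (master seed, configuration signature,
sample size), so the ledger is invariant to the number of work queues;
`workers` partitions candidates round-robin and results merge in canonical
order, which is the package's single-machine reading of multi-computer
round parallelism (the `m` switch round is accepted in config for interface
fidelity only).

**Finishing.** For the top two algorithms carrying an expensive-monotone
flag (forest/boosting tree counts: accuracy up, time proportionally up),
the flagged parameter of the best configuration is doubled past its search
cap, retraining on the full pool, until the gain is < 0.001 twice running
or the budget (8 steps) is spent; the incumbent is only replaced by a
strictly better model. Finally, forward stepwise selection with replacement
hill-climbs an ensemble over the 10 best models' stored test-sample
predictions, starting from the single best model and never accepting a
worsening step, so the ensemble's selection quality is ≥ the best single
model's by construction; weights are selection counts / total.

## 3. Projection

Each completed trial appends (t, best-so-far quality) to the accuracy
curve. The curve is fitted by f(t) = a − b·t^(−c) with 0 < b < a < 1,
c > 0, minimizing Σ (i/n)·(f(tᵢ) − yᵢ)² over the last n = min(g, h) points
(g = 20): later points carry more weight because the goal is prediction of
the future, not description of the past. The constraints are enforced by a
smooth reparameterization (a = logistic(α), b = a·logistic(β), c = exp(γ))
and the weighted SSE minimized by L-BFGS-B from 16 seeded starts — cheap,
derivative-friendly and deterministic. Times are shifted by +1 before
fitting so t^(−c) stays bounded near the origin; with fewer than 3 distinct
times the projection is simply "unavailable", not an error. Class-pair
confusion fractions p(c₁,c₂)(t), recomputed on the test sample whenever a
new best model appears, are fitted the same way — diagonal pairs increasing,
off-diagonal pairs with the decreasing form a + b·t^(−c) (b > 0, not
necessarily < a) — independently per pair and then row-renormalized to the
simplex, since nothing ties the independent fits together. The projected
expected outcome is Σ q(c₁)·p(c₁,c₂)·o(c₁,c₂) with user-supplied outcome
matrix o; continuous targets are discretized into quantile bins first.

## 4. Synthetic data: what it emulates, what it does not

The cohort generator draws event times from a homogeneous Poisson process
per attribute per patient (the simplest process with controllable rates)
and values from normal/lognormal/categorical distributions; the target is a
threshold (binary, with label-flip noise) or linear (continuous, with
Gaussian noise) function of exactly one planted (attribute, period,
operator) aggregate, so recoverability has a ground truth. Index dates
default to one per patient at the end of the horizon; multiple index dates
a year apart exercise the several-instances-per-patient case. The benchmark
generator's families fix which learner family is Bayes-optimal: the
axis-aligned rule family uses asymmetric sub-thresholds so the rule is
recoverable by greedy partitioning (a pure interaction rule would defeat
any greedy tree and make the family contract unverifiable).

What the generators deliberately do not emulate: clinical terminologies and
code hierarchies, informative missingness, measurement drift,
inter-attribute correlation structure, and irregular visit processes.
Passing tests therefore demonstrate the correctness of the machinery —
operators, selection, search, projection — on data whose generative
structure is known, not model quality on real EHR cohorts.

## 5. Problem sizes and numerical choices

The test suite and the acceptance script run the method at desk scale by
choice: cohorts of 150–2000 patients, benchmarks of 250–2000 rows,
candidate pools of a few hundred to 2000 where the production default is
10,000, and 3–5 seeds per Monte-Carlo claim. All such constants flow
through the same `search_control()` surface as the production defaults, so
scaling up changes a config value, not code. Quality is AUC for
categorical targets (macro one-vs-rest beyond two classes) and R² for
continuous ones. Missing values are median/mode-imputed per training fold;
timestamps are timezone-naive ISO-8601 compared as UTC. Degenerate inputs
are defined, not exceptional: empty EAV files read as empty tables,
single-candidate searches return that candidate, an initial sample
exceeding the pool collapses to a single round with a warning, and a search
in which every trial failed errors with the full ledger attached.

## 6. Known limitations

Evaluator potentials share trials with algorithm potentials, so an
evaluator unlucky in its algorithm pairings can be dropped early. The
scaled-estimate uplift is additive and ignores curvature in the learning
curve between the two sizes. The greedy reading of forward selection trades
wrapper fidelity for speed. Ensemble members are represented by stored
prediction vectors, so exporting the ensemble for new data means retraining
its members from the ledger. The inverse power law assumes the best-so-far
curve keeps saturating; regime changes (e.g. a new algorithm family
suddenly dominating late) are tracked only as fast as the i/n weights
forget the old regime.
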