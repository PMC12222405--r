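---
title: "Rule-guided preprocessing: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-guided preprocessing: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rstprep)
```

## The problem and the model

Small clinical cohorts with wide radiomics feature tables (tens of samples,
hundreds of features) force aggressive preprocessing before any classifier
can be trained: class-imbalance correction, outlier removal, redundancy
filtering and feature selection. Each of those steps makes decisions a
domain expert may want to influence — a feature known to be essential, a
sample known to be a protocol deviation — but conventional pipelines offer
no interface for that influence.

`rstprep` models clinician input as a *rule set table*: an ordered list of
directives `(scope, action, selector)` with scope `feature` or `sample` and
action `exp-keep`, `exp-remove`, `pref-keep` or `pref-remove`. The
semantics split into two classes:

* **Explicit** directives are constraints. `exp-remove` targets are deleted
  before any algorithm runs; `exp-keep` targets are guaranteed present in
  the final model. If a hard constraint cannot be honored (an explicit rule
  names a feature absent from the table, a feature budget smaller than the
  `exp-keep` set, removals that would empty a class), the pipeline stops
  with an error rather than silently degrading the clinician's requirement.
* **Preferential** directives are priors on the algorithms' own rankings.
  They bend a decision only when the target is "close enough" to the
  decision boundary, and are overruled otherwise. Closeness is
  operationalized by one interpretable tolerance per algorithm, collected
  in `preference_config()`:

  | parameter | algorithm | default | meaning |
  |---|---|---|---|
  | ε (`sfs_slack`) | SFS | 0.05 | relative score slack; a `pref-keep` candidate wins when its score ≥ (1−ε)·best; a `pref-remove` candidate is accepted only when its score > best-other/(1−ε) |
  | γ (`outlier_slack`) | isolation forest | 0.25 | quantile slack; `pref-remove` samples are removed within the top c(1+γ) quantile, `pref-keep` samples only within the top c(1−γ) |
  | w (`undersample_weight`) | undersampling | 4 | removal-draw weight multiplier (`pref-remove`: ×w, `pref-keep`: ×1/w) |

  At ε = γ = 0 and w = 1 every preferential rule is a no-op and each guided
  operator reproduces its unconstrained behavior exactly; the test suite
  asserts this bit-for-bit. The defaults were fixed once as moderate values
  — a 5% score slack is roughly the fold-to-fold noise of an inner CV
  estimate at these sample sizes; γ = 0.25 moves a 10% contamination cut
  between 7.5% and 12.5%; w = 4 makes a marked sample's removal odds
  clearly but not overwhelmingly different.

Two preferential behaviors have no tolerance knob by design. SMOTE ignores
preferential rules entirely (inventing per-sample synthesis preferences
would go beyond defensible semantics; only upstream explicit removals
change its input). The redundancy filter's preference is structural: within
a redundant group a `pref-keep` member *always* represents the group —
"keep my feature rather than its statistical twin" is a choice among
near-equivalent features, so there is no performance argument to overrule
it, and a `pref-remove` member never represents a group unless it is alone.

Precedence when several rules hit one target: explicit beats preferential;
within the same class the later line wins. A target under both `exp-keep`
and `exp-remove` is a fatal conflict reported with line numbers.

## Pipelines and evaluation protocol

The **manual pipeline** is fixed: explicit rules → SMOTE to a 1:1 class
ratio (k = 5 neighbors) → isolation-forest outlier removal (200 trees,
subsample 256, contamination 0.10) → SFS down to a per-cohort feature
budget (20 features for the 69- and 57-sample single-center twins, 10 for
the smaller dual-center twin, following the curse-of-dimensionality rule of
thumb of roughly n/3 training samples per retained feature). The stage
order — resample, then clean, then select — keeps the SFS inner CV
class-balanced and lets outlier removal see the synthetic points it should
judge; the order is recorded in every fitted pipeline's log so it is
auditable. Validation rows pass only through fitted, stateless transforms
(scaling parameters frozen from training rows, then feature subsetting);
they are never resampled or outlier-filtered, and a leakage test injects a
pathological validation row to confirm the fitted parameters cannot move.

The **MLDP search** is a seeded random search over pipeline compositions:
0–7 steps drawn from {SMOTE, undersample, isolation forest, redundancy
filter, z-score, min-max, SFS}, each at most once, SFS always last,
explicit rules always step 0 and never searched. Hyperparameters are drawn
from one declared block (contamination 0.02–0.2, SMOTE k 3–7, SFS k 5–30,
redundancy cutoff 0.8–0.98, undersample ratio 0.8–1.0). Candidates are
scored by mean balanced accuracy under 5-fold stratified inner CV,
re-seeded per candidate from the master seed; ties break toward the higher
score, then the shorter pipeline, then the lexicographically smaller
serialized specification, so the search is a pure function of
`(table, rules, budget, seed)`. Random search was chosen over a smarter
optimizer deliberately: it is reproducible, trivially auditable, and
sufficient to exercise the rule-dominance semantics that this package
exists to provide; its absolute scores are not claimed to match any
particular external AutoML system.

Evaluation uses Monte-Carlo cross-validation with an 80/20 stratified
split. The test-set size is round-half-up of 0.2·n (14 of 69), per-class
counts by largest remainder. Splits are a pure function of
`(n, folds, fraction, master_seed)`, so the 2 × 5 battery of one cohort
consumes byte-identical splits — fold-level comparisons between scenarios
are paired by construction. Dual-center cohorts are evaluated as a single
train-on-center-1 / test-on-center-2 fold. Scenario comparisons use a
one-way ANOVA of fold-level balanced accuracies against the no-rules
baseline (folds as replicates — the printed comparison in the source
experiments does not state its replication unit, so the simplest defensible
choice was fixed and documented), with CI95 = mean ± 1.96·SD/√F; dual-center
runs have one fold and report no p-value. Confusion ratios with a zero
denominator are reported as `NA`, never coerced to 0, and balanced accuracy
inherits that `NA`.

Classifiers are fixed and logged rather than tuned: XGBoost (300 rounds,
depth 4, eta 0.1), random forest (500 trees), RBF SVM with scale-style
gamma on internally standardized features, and a diagonal-LDA baseline.
The SFS wrapper scorer defaults to an incremental diagonal-LDA inner CV —
for a diagonal Gaussian discriminant the per-feature score contributions
are additive, so all candidates of a forward step are scored in one matrix
operation; the test suite verifies the fast path selects identically to the
explicit fold-by-fold scorer. Determinism throughout comes from a single
master seed expanded by `derive_seed()` (a string-tagged multiplicative
hash into [1, 2³¹−2]); score ties anywhere are broken lexicographically by
feature name or sample id at a 10⁻¹² tolerance.

## The synthetic twins

`cohort_preset()` reproduces the *shape* of three reference cohorts —
sample counts, feature counts, class imbalance, and for the dual-center
pair a nonzero batch shift (0.6 SD on all radiomics features of center 2):

```{r presets}
str(cohort_preset("dlbcl_twin"), give.attr = FALSE)
```

On that shape the generator plants structure that the guided operators can
be tested against: five informative features (additive shift of 0.8 SD in
the positive class — a "large" univariate effect that is still hard to find
among 150+ noise features at n = 69, which is exactly the regime of
interest), redundant groups built by mixing a parent with fresh noise to a
target intra-group correlation, a few whole-profile outliers at ±(6–10) SD,
three demographic-like columns (`age`, `weight_kg`, `height_cm`) so that
sample-level `where=` rules are exercisable, and optional label noise.
Class counts are exact (round-half-up), not expected values, and the table
is a pure function of the recipe.

What the twins do *not* emulate: real radiomics marginals (heavy tails,
mixed scales, block correlation across feature families), realistic
center effects beyond a mean shift, or any survival structure. Passing
tests on the twins therefore demonstrates that the rule semantics,
protocols and statistics behave as specified — not that any particular
accuracy level would transfer to patient data.

## Numerical and degenerate-input choices

* Constant features: z-score and min-max map them to 0; the correlation
  matrix treats their undefined correlations as 0 (they join no redundant
  group); the diagonal-LDA variance is floored at 10⁻⁸.
* Outlier removal never empties a class: the lowest-scoring removals of an
  endangered class are retained, and the guard is tested.
* Undersampling feasibility is checked up front: if `exp-keep` protections
  leave fewer removable majority samples than the target ratio requires,
  the step errors instead of silently missing the ratio.
* SMOTE requires k+1 minority samples and says so; already-balanced tables
  pass through unchanged.
* A failed cross-validation fold is recorded with its error message in the
  report, never silently dropped, and aggregates use the successful folds.

## Scale of the shipped experiments

The packaged tests and the reproduction script run the full protocol at
reduced replication chosen once for desk-scale experimentation: 30 shared
folds for the scenario-ordering experiment, 200 randomized draws for
hard-rule conservation, 50 repetitions for preferential monotonicity, 100
folds for the permutation null, and MLDP budgets of 3–15 candidates. The
protocol itself (split construction, reuse, metrics, comparisons) is
identical at 100 folds; only Monte-Carlo resolution changes.

## Known limitations

* Feature-scope rules select by name and glob only; feature-level clinical
  metadata (e.g. "all features from sequence X") would need a naming
  convention or an attribute table the format does not currently model.
* The preferential tolerances are global, not per-rule; a clinician cannot
  yet mark one suggestion as stronger than another except through rule
  scope.
* The ANOVA treats folds as independent replicates; Monte-Carlo folds
  overlap, so p-values are anti-conservative in absolute terms and are best
  read as paired-design comparisons on shared splits.
* Binary endpoints only; multi-class labels and survival endpoints are out
  of scope.
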