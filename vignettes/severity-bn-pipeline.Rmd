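---
title: "Modelling Alzheimer's disease severity with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Alzheimer's disease severity with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbn)
```

## The modelling problem

Alzheimer's disease (AD) presents through heterogeneous, coarse-grained
measurements: demographics, medical history, blood chemistry, the ApoE
genotype, psychological/functional assessments (MMSE, logical memory
immediate and delayed recall), and summary neuroimaging (total grey-matter,
white-matter and CSF volumes from MRI; active-voxel counts from amyloid
PiB-PET). `adbn` implements a hybrid pipeline that classifies AD severity
from such tables and — just as importantly — exposes the probabilistic
dependency structure among the measurements.

Severity is indexed by the Clinical Dementia Rating (CDR), an ordinal score
in \{0, 0.5, 1, 2, 3\}. The pipeline validates this choice by correlating
CDR against the clinical diagnosis (HC / MCI / AD) before modelling, and it
merges the mild and moderate classes (CDR 1 and 2) into one category
because moderate dementia is rare in ageing cohorts; the severe class is
treated as out of support. The working target therefore has three states:
*normal*, *very mild*, *mild/moderate*.

The pipeline runs, in order:

1. **Correlation validation** of CDR against diagnosis (Pearson, Fisher-z CI).
2. **Hold-out split** — a stratified 10% independent test set is set aside
   first; every later stage sees only the development set.
3. **Supervised discretization** — continuous features are cut by the CAIM
   criterion against the merged CDR classes; MMSE, ApoE and CDR use fixed
   clinical category schemes.
4. **Entropy-filter feature selection** under k-fold cross-validation.
5. **SMOTE class balancing** of the development set.
6. **Scoring-function selection** for structure learning, by cross-validated
   log-likelihood loss over K2 / BDe / mBDe / BIC.
7. **Constrained hill-climbing** structure search.
8. **CPT fitting** (Laplace smoothing for prediction).
9. **Evaluation** on the held-out test set: multi-class accuracy with a
   Clopper-Pearson interval, macro one-vs-rest AUC, per-class sensitivity
   and specificity, and arc strengths.

## The models and statistics

**CAIM.** For a candidate set of cut points, the quanta matrix `q[s, r]`
counts class `s` in interval `r`. The criterion
\[
CAIM = \frac{1}{n}\sum_{r=1}^{n} \frac{\max_r^2}{M_{+r}}
\]
(with `max_r` the largest class count and `M_{+r}` the total in interval
`r`) rewards class-pure, well-populated intervals. `caim_discretize()`
inserts midpoint boundaries greedily: a boundary is accepted while it
strictly improves the criterion, or while the scheme still has fewer
intervals than target classes; growth also stops at `max_intervals`
(default 3, the number of merged severity classes). Intervals are
left-open/right-closed with infinite outer bounds, so a frozen scheme is
total on unseen data — required for honest held-out evaluation. Greedy ties
break toward the smaller cut point, making the procedure deterministic.

**Entropy filters.** With `H` the Shannon entropy (base-2, plug-in
estimates, no smoothing),
\[
IG = H(C) + H(A) - H(C, A),\qquad
IGR = IG / H(A),\qquad
SU = 2\,IG / (H(C) + H(A)).
\]
`select_features()` ranks features by all three filters inside each CV
fold; a feature is *selected* in a fold when it is in the top-`keep` of all
three simultaneously, and the final set holds features selected in 100% of
folds. Two behaviours deserve note:

* Gain ratio is unstable for near-constant attributes (tiny `H(A)`
  denominators), which CAIM can produce on uninformative continuous
  features by isolating small extreme intervals. We therefore apply the
  C4.5-style eligibility gate: features below the fold-median information
  gain rank after the rest in the IGR list.
* Because k-fold training sets share most rows, within-sample rank
  stability is *not* a permutation-null guarantee: in an all-noise universe
  a few features can reach 100% within-sample frequency. What the null does
  deliver — and what the tests assert — is non-replication: stable sets
  from independent noise cohorts are disjoint, and noise never displaces
  genuine signal features.

**SMOTE.** Each synthetic minority record interpolates a record and one of
its k nearest minority neighbours (`x + u(z - x)`, u uniform), with a
mixed-type distance: Euclidean over numeric and ordinal-coded coordinates
plus a unit penalty per nominal mismatch. Ordinal results are rounded to
the nearest valid code; nominal coordinates take the neighbourhood majority
(ties to the seed record). Balancing raises every class exactly to the
majority count and flags synthetic rows, so the operation is invertible.
Two placements are available: `smote_policy = "fold"` (default) balances
inside CV training folds only, avoiding leakage into validation folds;
`"development"` balances the whole development set before CV, reproducing
the classical workflow at the cost of optimistic CV estimates. The
held-out test set is never balanced under either policy.

**Structure scores.** All four family scores are decomposable and computed
in log space with natural logarithms: K2 (Cooper-Herskovits with all-ones
Dirichlet), BDe (BDeu with equivalent sample size `ess`, default 10), mBDe
(interpreted as BDe with per-parent-row prior mass `ess * N_j / N`; rows
never observed carry no prior mass), and BIC
(`loglik - (d/2) log N`, `d = (r-1) q`). BDe satisfies covered-edge score
equivalence, which the tests verify.

**Constrained hill climbing.** The search applies single-arc additions,
deletions and reversals, always keeping the graph acyclic, respecting
forbidden arcs, never deleting required arcs, and honouring tier
constraints that encode the clinical causal ordering: \{age, ApoE\}
→ \{GM, WM, CSF, PiB-PET\} → \{CDR\} → \{MMSE, LMIR, LMDR\}, with
within-block arcs free. The best strictly positive gain is applied (ties
to a fixed enumeration order, so the search is deterministic given the
data); family scores are cached so only changed families are re-scored.

**Inference.** `predict_class()` is exact variable elimination over the
CPT factors; posteriors match full joint enumeration to 1e-10 in the test
suite. Hard classifications take the posterior argmax with ties broken
toward the more severe class — the clinically conservative choice.

**Evaluation.** Multi-class accuracy uses the exact Clopper-Pearson 95%
interval (the CI method is a package decision; the convention is not
universal). Multi-class AUC defaults to the macro average of one-vs-rest
midrank AUCs computed from posterior probabilities, with a Hand-Till-style
pairwise variant available (`method = "hand_till"`); classes absent from
the truth are excluded with a warning, not silently zeroed. Undefined
sensitivities/specificities are reported as missing, never as 0.

## The synthetic cohort generator

The real study data this pipeline is aimed at is access-restricted, so the
package ships a generator whose ground truth is known, making every stage
testable end to end.

The generator's core is a nine-node discrete network
(`default_truth_network()`): age and ApoE drive amyloid burden (PiB-PET),
which together with age drives grey-matter atrophy and CSF volume; the
three biomarkers drive the merged CDR; CDR drives MMSE, LMDR and LMIR, with
an extra LMDR → LMIR arc. Effect sizes are deliberately asymmetric —
cognitive links strong, biomarker-to-severity links weaker — matching the
qualitative regime the pipeline is designed to detect, and ApoE acts
through an epsilon-4 dose effect. Per subject-visit, the raw CDR is drawn
from the configured prevalences (0.72 / 0.21 / 0.05 / 0.02 over CDR
0 / 0.5 / 1 / 2, with an 8% per-visit progression drift); the eight signal
features are then drawn *jointly* from the network conditional on the
merged class (exact conditional draws by rejection), and continuous values
are emitted around state-specific means. The remaining 24 dictionary
features are severity-independent noise. The diagnosis label is drawn from
a CDR-conditional table calibrated so that the implied diagnosis-CDR
Pearson correlation is about 0.8, the regime in which using CDR as the
severity index is defensible. Missingness is modality-structured — a
skipped MRI drops GM/WM/CSF together (25%), PET 35%, the blood panel 5% —
because that is how cohort data actually goes missing, and it keeps
complete-case fractions realistic (roughly 630 complete subject-visits of
about 1480).

Every randomised operation derives its stream from one master seed plus an
operation name (`substream_seed()`), so adding a stage never shifts another
stage's draws and runs are exactly reproducible.

What the generator does **not** emulate: real AIBL summary statistics,
within-block biomarker correlations beyond the network skeleton,
informative (severity-dependent) missingness, measurement drift across
visits, or any mechanistic progression model. Consequently, passing tests
demonstrate correctness of the algorithms and recoverability under
known-truth conditions — not clinical performance. The synthetic cognitive
links are close to deterministic after discretization, so accuracy metrics
on synthetic cohorts (MCA and AUC near 1) are optimistic relative to any
real cohort.

## Numerical choices and degenerate inputs

* Base-2 logarithms for entropies (bits); natural logarithms for all
  network scores and likelihood losses.
* CPT smoothing: 0 for score computation (the Dirichlet scores embed their
  own priors), 1 (Laplace) for prediction; unseen parent configurations
  receive the uniform row.
* A record with zero probability under an unsmoothed model yields an
  infinite loss with a warning rather than a silent `NaN`.
* Degenerate discretization inputs (constant feature, single class, empty
  interval) raise typed errors; the pipeline surfaces them with the stage
  name rather than imputing.
* No imputation anywhere: analyses are complete-case with respect to the
  features they use, and group assembly resolves "complete at least once
  later" by the earliest complete later visit per subject.
* If no feature attains 100% selection stability, the pipeline falls back
  to the `keep` most stable features rather than failing, and records this
  in the manifest-visible selection report.

## Problem sizes used by the test-suite

The suite exercises structure recovery at n = 5000 over 10 seeds (median
skeleton recall at least 80%, at most 2 false positives), parameter
recovery at n = 100000 for parent configurations with adequate occupancy
(estimation error of a CPT row scales with that row's realization count,
so rows essentially never visited are excluded from the tolerance), exact
inference against enumeration on 100 random networks of up to 10 nodes,
and the full pipeline on cohorts of 450-861 subjects. These sizes are the
package's choices for stable, repeatable statistical assertions.

## Known limitations

* Static networks only: time slices are compared (`compare_networks()`,
  `run_longitudinal_experiment()`), not modelled jointly as a dynamic BN.
* Discrete BNs only; continuous features must pass through discretization.
* The mBDe prior and the equivalent sample size are interpretations
  exposed as configuration, as is the exact MMSE band convention
  (24-30 / 19-23 / 10-18 / 0-9).
* Arc strengths by conditional G-squared tests condition on the child's
  other parents; marginal tests would give different p-values.
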