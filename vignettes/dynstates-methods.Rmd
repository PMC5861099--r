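---
title: "Models and methods behind dynstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dynstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state functional connectivity is usually summarized by one
correlation matrix per scan. `dynstates` instead treats the correlation
structure as time-varying: overlapping sliding windows yield a sequence
of connectivity estimates per scan, recurring configurations ("brain
states") are estimated by k-means over pooled windows, and everything
downstream — state hierarchy, dwell/transition dynamics, individual
fingerprinting, case-control comparisons, and symptom prediction from
state-specific network strength — is built on those states.

The package is organized so that every analysis stage can be validated
against ground truth: a synthetic-cohort generator plants known latent
states, subject fingerprints, group effects and symptom signatures, and
the test suite recovers them with the same code paths a real cohort
would use.

## Windowed connectivity

A run is a $T \times R$ parcel time-series matrix (defaults $T = 120$
usable time points at a 3 s sampling interval, $R = 114$ regions in 17
networks). Rectangular, untapered windows of width 11 time points
(33 s) advance by 1 time point, giving $T - w + 1 = 110$ windows per
run. Each window's Pearson correlation matrix is Fisher
z-transformed, $z = \operatorname{artanh}(r)$, with $|r|$ clipped at
$1 - 10^{-7}$ so duplicated signals stay finite. Matrices are stored as
edge vectors: the upper triangle in row-major order, diagonal excluded,
giving $R(R-1)/2 = 6441$ edges at $R = 114$.

Numerical choices: a window with a zero-variance region is an error
(named, not silently dropped); the window count formula
$\lfloor (T-w)/s \rfloor + 1$ is exact for every geometry; the stride
is 1 because 110 windows from 120 time points forces it.

## State estimation and instability

Pooled window vectors are clustered by standard squared-Euclidean
k-means (Lloyd iterations in compiled code, kmeans++ initialization,
10 restarts, deterministic seeding, empty clusters reseeded to the
worst-fit point). States are renamed after clustering in order of
descending occupancy, so state A is always the most-occupied solution
member.

Two solutions are aligned by the Hungarian algorithm on the cost
$1 - \operatorname{cor}(\text{centroid}_i, \text{centroid}_j)$; the
assignment solver is an $O(n^3)$ shortest-augmenting-path
implementation validated against brute-force permutation enumeration.

Split-resampling instability: for each candidate $K$ and each
replicate, windows are split into random halves and half the edges are
independently subsampled; each half is clustered on the shared edge
subspace and the halves are Hungarian-matched; the replicate deviation
is the total matched dissimilarity and instability($K$) its mean over
replicates. Stable solution sizes are strict local minima of the curve
(endpoints only if below their single neighbour). Two practical points
discovered while validating:

* the split must be over the *full* window pool. Splitting an already
  1/10-subsampled pool leaves so few windows per half that centroid
  sampling noise dominates and the curve is monotone in $K$; with the
  full pool the curve shows the expected local minima (at $K = 2$ and
  the planted $K = 4$ on synthetic cohorts).
* the deviation sum has a noise floor that grows with $K$; the local
  minimum at the true $K$ emerges because forced merges (at $K-1$) and
  arbitrary splits (at $K+1$) disagree across halves.

The edge-axis subsample fraction (50%) is a declared choice; nothing in
the method pins it.

## Hierarchy

To ask whether the $(S+1)$-state solution subdivides the $S$-state
solution, every pair of child states is merged into a "hybrid" (their
element-wise centroid mean), the resulting $S$-state atlas is
Hungarian-matched to the parent, and the minimum-cost pair wins (ties
break lexicographically). Chaining adjacent levels yields a tree; on
nested synthetic splits the selected pair is the planted split, and the
most-occupied state traces a single lineage across levels — the
attractor.

## Dynamics

Windows are assigned to the nearest centroid by Pearson correlation
(ties to the lowest-index state). Dwell time is the fraction of a
subject's windows in each state (the odds-like reading "time in S
relative to time in not-S" is exposed as `mode = "odds"` but not
endorsed). Persistence is $\Pr(\text{stay})$ estimated from
consecutive-window counts; the conditional switch matrix row-normalizes
off-diagonal transitions over switches only, and rows for unvisited or
never-left states are `NA`, flagged, never zero-filled. Transitions are
never counted across run boundaries. Overlapping windows autocorrelate
these estimates; the package reports them as observed quantities and
makes no small-sample correction (a documented caveat, as in the
empirical literature).

## The synthetic cohort

The generator is a stated world, not a tuning knob; its defaults were
fixed while building the package and are justified here.

* **Latent dynamics.** States switch at time-point resolution via a
  Markov chain whose initial state is the stationary distribution.
  Default self-transitions are 0.97 (attractor) and 0.94 (others), with
  two thirds of the leaving mass directed to the attractor: expected
  dwell runs of ~33 and ~17 time points comfortably exceed the
  11-point window. This is a *well-posedness* requirement, not a
  convenience — if typical dwell is shorter than the window, almost
  every window mixes states and no window-based method can resolve
  them. Ground truth is emitted at both time-point and window
  resolution (majority state per window; ties to the centre time
  point).
* **State geometry.** Each non-attractor state owns an equal-sized
  subset of networks: within-network coupling 0.60 on its own networks
  and 0.25 elsewhere, cohesive between-network coupling (0.30) inside
  its set, anticorrelation (-0.15) to the rest, baseline 0.05. The
  attractor is a muted 0.5× copy of the average non-attractor pattern:
  uniformly the lowest within-network coupling, globally structured —
  mirroring the empirical observation that the most-occupied state
  resembles the static connectivity pattern with a flattened profile.
  Differences confined to within-network blocks alone are *not*
  recoverable at 11-sample window noise; distributing them across the
  matrix is what real connectivity states do.
* **SPD repair.** Block-built matrices and all perturbed matrices are
  repaired by eigenvalue flooring at $10^{-6}$ and renormalization to
  unit diagonal. Perturbations large enough to make the repair bind
  systematically bias the realized covariance away from the planted
  one; the default fingerprint SD (0.02) is deliberately below that
  threshold.
* **Fingerprints.** One symmetric perturbation per subject, drawn once
  and reused across every state, run and visit.
* **Symptom machinery.** Patients carry a scalar liability
  $l_i \sim N(0,1)$ that shifts the designated symptom edges of the
  symptom state only (default SD 0.12 per unit liability); the
  active-psychosis label is Bernoulli with
  $\Pr = \operatorname{logistic}(\beta \cdot \tilde s_i)$ where
  $\tilde s_i$ is the standardized sum of the subject's *true*
  symptom-state edge z-values — the same logistic form the prediction
  module fits, so the planted signal is recoverable by construction.
  PANSS-like scores are drawn with the published present/absent means
  and SDs (positive 19.90 ± 5.67 vs 8.88 ± 2.20, and analogously for
  the negative and general scales).
* **What the generator does not emulate:** hemodynamics, physiological
  and scanner noise spectra, motion, site effects, spatial
  autocorrelation of parcels. A green test therefore establishes that
  the *analysis machinery* recovers planted structure, not that the
  method is robust to fMRI artifacts.

## Group statistics

All group comparisons first residualize on nuisance covariates by OLS
(rank-deficient designs fail loudly, naming the collinear columns).
Edgewise comparisons are pooled-variance two-sample tests (one-way
ANOVA $F = t^2$) with Benjamini–Hochberg FDR across the edges of one
state; network-level tests compare subject-level mean within-network z
with Bonferroni correction over the tested family; dwell comparisons
are the same machinery on dwell fractions. The cross-state coefficient
of variation uses the sample SD and reports `NA` for near-zero-mean
networks instead of exploding; networks are compared by a one-way
repeated-measures ANOVA with clustering solutions as the repeated
measure.

## Fingerprinting

Per-state mean connectivity profiles from two sessions are correlated
across all subject pairs; identification ranks each subject's own
session-2 profile among all session-2 profiles (rate = fraction of
rank-1 matches) against a null built by shuffling session-2 labels,
with the add-one permutation p-value. The between-subject pool includes
both orderings. Subjects missing a state in either session are excluded
pairwise for that state.

## Symptom prediction

Edges of a state's training profiles are screened by Pearson
correlation with the binary label at $p \le 0.05$ and split by sign;
network strength is the *sum* of a subject's selected-edge z-values
(sum vs mean differs by a scale factor absorbed by the slope);
an elastic-net logistic model
$\hat p = \operatorname{logistic}(\hat\beta_0 + \hat\beta_1 s + \hat{\boldsymbol\gamma}^\top \mathbf c)$
is fit with glmnet ($\alpha = 0.5$; $\lambda$ by an in-package inner
CV over glmnet's path, one-standard-error rule by default; the
`lambda.min` rule is available and is the better choice when the
quantity of interest is cross-state AUC *contrast*, which aggressive
shrinkage flattens at moderate $n$). Three numerical decisions deserve
emphasis:

* **Leave-one-out ROC uses the intercept-free score**
  $\hat\beta_1 s_i + \hat{\boldsymbol\gamma}^\top \mathbf c_i$. The
  fold intercept tracks the leave-one-out class composition and by
  itself drives null AUC far below 0.5; excluding it removes exactly
  that artifact and cannot change the ranking within any single fitted
  model.
* **Permutation tests freeze the edge signatures.** Following the
  method's own description, selection is performed once on the observed
  labels and only the logistic weights are refit under each permuted
  label vector. Rerunning selection inside the permutation loop leaves
  a selection-coupling pessimism (null mean AUC ≈ 0.48 at $n=91$)
  that contradicts the intended chance-symmetric null.
* **Holdout evaluation never refits**: feature sets and weights are
  frozen from training; only holdout labels are permuted for its
  p-value.

The 70/30 split is stratified with largest-remainder rounding, so 130
subjects give exactly 91 training and 39 holdout. PANSS-style scores
binarize at mean − 1 SD with the boundary assigned "high".

## Known limitations

Window overlap autocorrelation is uncorrected; the instability curve's
absolute scale depends on pool size (only its shape is interpreted);
identification of sparsely expressed states is limited by
windows-per-state, not by the fingerprint; LOOCV AUC retains a small
$O(1/n)$ pessimism even with the intercept-free score; and the
synthetic world's Gaussianity makes every correlation estimator behave
slightly better than on real BOLD data.
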