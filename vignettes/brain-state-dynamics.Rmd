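---
title: "Modelling brain-state dynamics in ROI time series with Gaussian HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling brain-state dynamics in ROI time series with Gaussian HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynstates)
```

## The model

Resting-state BOLD activity, parcellated into $R$ regions of interest and
sampled every TR seconds, is treated as a realisation of a hidden Markov
model with $K$ recurring whole-brain *states*. While state $k$ is active,
the $R$-dimensional observation is multivariate normal with state-specific
mean activity $\mu_k$ and covariance $\Sigma_k$; the active state evolves
as a first-order Markov chain with row-stochastic transition matrix $A$
and initial distribution $\pi$. One model is fitted to *all* subjects
jointly — each subject contributes an independent sequence sharing the
same states and dynamics — because group comparisons only make sense when
the two groups are described in a common state space. A per-subject
alternative (re-estimating transitions per subject by EM) would confound
estimation noise with group differences at the sequence lengths typical
of resting-state fMRI (a few hundred volumes), so subject-level dynamics
are instead summarised from decoded paths (below).

Key assumptions, and where they bite:

* **Gaussian emissions.** Scale heterogeneity across regions otherwise
  dominates the likelihood, which is why per-region z-scoring
  (`standardize()`, sample SD with denominator $n-1$) is on by default
  before fitting. The amplitude information this style of analysis
  cares about survives in the *relative* pattern of each state's mean.
* **Geometric dwell times.** A first-order chain implies geometrically
  distributed visit durations per subject. When subjects differ in their
  transition probabilities, the *pooled* dwell distribution is a mixture
  and is no longer geometric; the fitter's refinement step (below) exists
  largely because of this.
* **Shared states across subjects and groups.** Violations would appear
  as near-empty states in one group; the occupancy diagnostics surface
  this.

## Fitting: EM, initialization, and the split-merge refinement

`fit_hmm()` maximises the likelihood by Baum–Welch EM. All recursions run
in log space with log-sum-exp rescaling and Cholesky-based Gaussian
log-densities, so a 220-timepoint, 116-region problem is numerically
unremarkable. A ridge of $10^{-6} \times$ the mean diagonal is added to
every M-step covariance. Convergence is declared when the relative
log-likelihood improvement falls below `tol` (default $10^{-6}$), with a
cap of `max_iter` iterations; the log-likelihood trace of the winning run
is checked to be non-decreasing in the test suite.

EM only finds local optima, and two failure modes recur at realistic
sizes:

1. **Duplicate states.** With between-subject heterogeneity in
   transitions, a second copy of a high-occupancy state buys genuine
   likelihood by modelling dwell-time mixtures. The copies have
   near-identical means.
2. **Absorbed clusters.** A state with low occupancy (a few percent) is
   swallowed by a neighbour whose covariance widens to cover it, and its
   timepoints are *not* conspicuously badly fit afterwards.

Three layers address this. Restarts (default 10) alternate two
initialization styles: k-means++-seeded k-means with the within-cluster
pooled covariance (finds small, well-separated clusters) and stock
k-means with the total covariance (reaches the broader, sometimes
subject-specialised optima). After the best restart is chosen, a
deterministic, likelihood-guided *split-merge refinement* (`n_rescues`,
default 2) frees one state of the closest mean pair, re-seeds it on the
minor mode of the most bimodal state (screened by a within-state 2-means
gain), re-runs EM, and keeps the move only if the log-likelihood
improves. On the package's own 12-state diagnostic cohort this moves the
fit from a solution missing a 3%-occupancy state (decoding accuracy 0.81)
into the ground-truth basin (accuracy ~0.94) — the improvement is
computed, not assumed, in `tests/testthat/` and the acceptance script.
Finally, states whose total responsibility drops below $R + 1$ timepoints
are re-seeded from the worst-fit observations, at most twice per state.

Decoding defaults to the per-timepoint argmax of the marginal posterior
$\gamma$ (`decoder = "gamma"`), because fractional occupancy is naturally
a $\gamma$ quantity; the joint MAP path (`viterbi`, ties broken toward
the lower state index) is always computed alongside. On well-separated
data the two disagree on well under 5% of timepoints, a consistency the
tests assert.

## Choosing the number of states

`select_model_order()` fits every candidate $K$ and reports
$\mathrm{BIC} = -2\log L + p\,\log T_{\mathrm{tot}}$ with
$p = (K-1) + K(K-1) + KR + KR(R+1)/2$, plus an occupancy degeneracy
diagnostic: a state is *near-empty* when its median fractional occupancy
across subjects falls below $1/(10K)$. BIC here plays the role the
variational free energy plays in Bayesian HMM toolboxes — both trade fit
against complexity — and maximum-likelihood EM with BIC was chosen over
variational inference because it is fully specifiable from the model
statement above and auditable against brute-force oracles. The chosen
$K$ is the smallest candidate within one BIC standard error of the
minimum (SE estimated from the between-subject spread of per-subject
deviances) that has no near-empty states; the full report is returned so
the choice can be overridden. Over-specified models on heterogeneous
cohorts tend to park their surplus states on individual subjects, which
is exactly what the median-across-subjects occupancy flag detects.

## Per-subject dynamics

From each decoded path the five standard temporal-dynamics summaries are
computed (`subject_dynamics()`):

* **Fractional occupancy** — proportion of timepoints per state.
* **Mean lifetime** — mean visit duration; a visit spanning samples
  `start..end` contributes `(end - start + 1) * TR` seconds, i.e. every
  occupied sample counts one TR of dwell. Never-visited states give NaN.
* **Mean interval** — mean time strictly between consecutive visits to a
  state. Time before the first and after the last visit is censored, not
  an interval, so states visited at most once give NaN.
* **Switching rate** — state changes divided by `(T - 1) * TR`. This
  denominator (rather than `T * TR`) makes the identity
  `switching_rate = (T - 1 - trace(counts)) / ((T - 1) * TR)` exact,
  which the tests exploit; the per-state variant (exits from $k$ per
  second spent in $k$) is emitted alongside.
* **Transition matrix** — row-normalised adjacent-pair counts including
  self-transitions (group tests default to this view), with an
  off-diagonal view (diagonal zeroed, rows renormalised) for analyses of
  between-state switching only.

NaN entries are excluded pairwise from group tests with the per-state
sample sizes recorded.

## Group inference

`compare_metric()` runs two-tailed two-sample t tests (pooled-variance
Student by default, Welch by flag) per state, with Benjamini–Hochberg
FDR applied within each metric's family of $K$ states — four families,
matching how such results are conventionally presented per metric; a
pooled family is a configuration away. `permutation_test_transitions()`
tests every ordered state pair by the difference of group means of the
subject-level transition probability; one label shuffle per permutation
serves the whole matrix, preserving dependence between entries, and the
two-sided p value uses add-one smoothing
$p = (1 + \#\{|d_{\mathrm{null}}| \ge |d_{\mathrm{obs}}|\})/(B + 1)$ so
p is never exactly zero. The mean difference (not a t statistic) is the
permutation statistic — the simplest choice consistent with building a
null distribution of differences. `partial_spearman()` implements
covariate-adjusted rank correlation: ranks of x and y are residualized
on the (rank-transformed) covariates by least squares and the Pearson
correlation of residuals is reported, with a t-approximation p value on
$n - 2 - c$ degrees of freedom. Cognitive-impairment contrasts split
subjects at a MoCA score of 26, with scores exactly at the cutoff
assigned to the unimpaired group and counted in a boundary report, since
screening conventions are ambiguous at the boundary.

## The synthetic cohort generator

No suitable public dataset accompanies this class of analysis, so
`simulate_cohort()` generates what the pipeline needs with full ground
truth retained: per subject, a transition matrix (base matrix ×
multiplicative group effects on targeted entries × per-subject
log-scale jitter, rows renormalised at each stage), a sampled state
path, and Gaussian observations drawn through per-state Cholesky
factors. Per-subject RNG substreams derived from the single spec seed
make every subject's data independent of cohort ordering, and the whole
cohort a deterministic function of the spec.

`default_paper_like_spec(scale)` encodes the study-shaped defaults: 12
states, 116 regions, 220 timepoints at TR 2 s and a 71/57 two-group
cohort at `scale = 1`, shrinking regions and group sizes proportionally
(floors: 8 regions, 5 subjects per group). Its design choices, fixed
once after pilot simulations and not revisited:

* **Sticky, structured transitions.** Diagonal ≈ 0.85 before
  renormalisation, a weak cyclic pathway, and a *hub* state (state 7)
  with elevated inflow (+0.08 from every other state) and a strong edge
  to state 1 (+0.18). The hub exists so that planted multiplicative
  effects on a directed edge are identifiable at reduced scale: power
  for detecting a 1.6× effect on the 7→1 edge at `scale = 0.3` was
  piloted at ~0.92 (200 replicate cohorts, 999 permutations). Weaker,
  uniform off-diagonal designs put so few transitions through any single
  edge that no test could see a plausible effect at desk scale.
* **State means** are sparse ±(1.5, 1.0) patterns on stride-$K$ region
  sets, which are mutually disjoint for any $K \le R$ — amplitudes at
  which the states are reliably decodable (accuracy ~0.94 at
  `scale = 0.25`), mirroring the robust state estimation reported for
  real cohorts of this size.
* **Covariances** are identity-plus-rank-one with condition number well
  under $10^3$, keeping EM well-posed.
* **Group effects**: patients have all inflow into state 3 damped by
  0.55, producing reduced state-3 occupancy; the simulated MoCA score
  (truncated normal around 26) gains a positive dependence on state-3
  occupancy so correlation analyses have a planted signal. Ages
  ~N(44, 10) in [18, 80] and education ~N(12, 3) ≥ 0 are scenery for the
  covariate-adjustment code paths, not inference targets.
* **Subject jitter** (SD 0.10 on log transition probabilities) supplies
  realistic between-subject variance; it is also what makes group-level
  fitting genuinely hard (see the split-merge discussion), which is a
  feature in a validation harness.

What the generator does **not** emulate: hemodynamic convolution,
scanner drift, motion artefacts, spatial autocorrelation of
parcellations, or non-Gaussian heavy tails. Passing tests therefore
demonstrate correctness of inference and statistics under the stated
model, not robustness to the full messiness of real fMRI.

## Problem sizes and numerical choices in the test suite

The suite exercises the same design at reduced size so that a complete
run stays in the low minutes: exhaustive-enumeration oracles for the
forward–backward evidence and Viterbi path at $K \le 3$, $T \le 8$
(where summing all $K^T$ paths is feasible); parameter recovery and
order selection on a well-separated $K = 3$, 8-region, 20-subject,
220-timepoint cohort; t-test calibration on 500 null replicates of
1000-per-group samples; permutation calibration on 200 null cohorts at
999 permutations; the planted-effect power check on 50 replicate
cohorts at `scale = 0.3` using ground-truth paths (isolating the
statistical layer from the fitter, which has its own recovery checks);
and 20 end-to-end no-effect pipeline runs for the FDR false-positive
check. Calibration rates are assessed pooled across exchangeable
states/entries, matching the Monte-Carlo precision those replicate
counts afford. Tie-breaks everywhere go to the lower state index;
degenerate inputs (constant regions, unvisited states, all-identical
groups, rank-deficient covariates) have defined, tested behaviour.

## Known limitations

* Maximum-likelihood EM with BIC, not variational Bayes: no posterior
  uncertainty over model parameters, and BIC's complexity penalty is
  asymptotic.
* The group-level model has no explicit subject random effects;
  between-subject transition heterogeneity is summarised post hoc from
  decoded paths rather than modelled.
* Hard (argmax) decoding underlies the dynamics metrics by default; a
  soft occupancy is emitted for sensitivity but lifetimes/intervals have
  no soft analogue here.
* The permutation test assumes exchangeability of subjects under the
  null; covariate imbalance between groups is not adjusted for in that
  test (it is in the correlation analysis).
* `extract_roi_timeseries()` averages voxels within labels; no
  weighting, eroding, or partial-volume handling.
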