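---
title: "Decoding ultimatum-game decisions from simulated real-time fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding ultimatum-game decisions from simulated real-time fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A responder in the repeated ultimatum game sees an offer splitting a 3-euro
stake and, a few seconds later, accepts or rejects it. Rejections of unfair
offers (20% of the stake or less) are frequent even though they cost the
responder money — altruistic punishment. The question this package addresses
computationally: can the upcoming decision be predicted from BOLD fMRI
activity *before* the response is given, using only the ten seconds of data
that follow the offer?

`ugdecode` implements the full analysis stack for that question against
synthetic data with known ground truth:

* a paradigm generator (offer schedules, logistic responder behavior,
  payoffs),
* a 4D BOLD simulator with class-dependent region-of-interest (ROI)
  activations, linear drift and AR(1) noise,
* online feature extraction (per-trial t-values of three ROIs),
* a sparse Bayesian relevance vector machine (RVM) classifier retrained
  after every revealed trial,
* permutation-based empirical guessing levels,
* offline whole-brain linear SVM analyses (cross-validation schemes,
  balanced choice-versus-value resampling, adjacent-offer discrimination),
* back-projection of SVM weights with permutation significance and
  cluster-extent filtering.

## Trial structure and timing

Each trial lasts 22 s: the stake is shown for 2 s, the offer for 12 s, the
response screen for 4 s and the payoff for 4 s. With a repetition time of
2 s a 60-trial session spans 660 scans. All scan indexing counts from the
offer onset: "scan 1" is the first volume acquired at or after the offer
appears. Scans 1–2 (first 4 s) form the baseline window; scans 3–5
(seconds 6–10) form the active window, consistent with the ~5 s build-up
of the hemodynamic response. The decoder must commit to a prediction
before the response screen at 14 s — in this implementation the prediction
is logged at offer onset + 10 s, once scan 5 is complete.

The five offer types (proposer:responder) appear 6 (50:50), 8 (65:35),
12 (70:30), 21 (80:20) and 13 (90:10) times per session, in a uniformly
shuffled order; no further randomization constraints (such as no-repeat
rules) are imposed.

## Synthetic responder behavior

Decisions are drawn from a two-parameter logistic in the responder's
share: `P(accept) = plogis((share - threshold) * slope)` with defaults
`threshold = 0.25`, `slope = 30`. This is the simplest generator that
reproduces the characteristic behavioral cliff between the 70:30 and
80:20 offers (acceptance ~82% at a 30% share, ~18% at 20%) while keeping
even splits almost always accepted and 90:10 offers almost always
rejected. The two parameters are exposed so alternative behavioral regimes
(e.g. more tolerant responders) can be simulated.

## The BOLD simulator

Every trial adds a boxcar covering the 12 s offer phase, convolved with a
double-gamma hemodynamic response function (response gamma with shape 6,
rate 1 — mode at 5 s — minus a 1/6-amplitude undershoot with shape 16; the
curve is scaled to unit peak), to the voxels of each ROI. The amplitude
depends on the upcoming decision. The defaults encode the signal pattern
that motivates the ROI choice: anterior insula (AI) and lateral prefrontal
cortex (LPFC) activate before rejections (amplitude 1 baseline-percent
unit on reject, 0 on accept), the occipital cortex (OC) before acceptances
(1 on accept, 0 on reject). A `nonspecific_response` term adds a
class-independent response to every offer and is used to emulate
subject-specific shifts (see retraining below). Voxel noise is stationary
AR(1) Gaussian (innovation SD 0.5, lag-1 coefficient 0.3) plus a linear
drift of 0.01 units/scan, so the detrending stage does real work.

ROIs are volume-exact spheres: the N = round(volume / 27 mm³) lattice
voxels nearest each tabulated center (LPFC ±50, 28, 11 at 3798 mm³ per
side; AI ±38.5, 20, −1 at 2925 mm³; OC 0, −88, 3 at 15606 mm³). Left and
right masks are pooled before feature extraction. The default simulation
grid is a 3 mm MNI-lattice box cropped to contain the three ROIs; the full
61×73×61 MNI grid is available via `mni_grid()`. `sim_config(noise_scope
= "roi")` restricts noise generation to ROI voxels — statistically exact
for every analysis that only reads ROI signal, and used throughout the
test suite for speed.

What the simulator does *not* emulate: head motion (assumed corrected
upstream, e.g. on-scanner), physiological noise spectra, spatial noise
correlations, susceptibility artifacts, and any cross-trial adaptation of
the responder. Passing tests therefore demonstrate the correctness and
statistical behavior of the *analysis machinery* under a favorable,
well-specified generative model — not performance on real data.

## Online features and classifier

Per trial, the pooled ROI-mean series (linearly detrended over all scans
acquired so far) is reduced to one pooled-variance two-sample t-value per
ROI — active window (scans 3–5) minus baseline (scans 1–2), 3 degrees of
freedom. The pooled-variance form is used (a Welch variant would differ
only in degenerate trials at these window sizes); on null data the
features are verified to follow a Student t(3) distribution. A trial with
zero pooled variance yields t = 0 when the mean difference is zero and a
signed cap of ±1e6 otherwise.

The classifier is a relevance vector machine: kernel logistic regression
with independent Gaussian priors on the basis weights whose precisions are
estimated by type-II maximum likelihood. Training uses the *sequential*
(constructive) fast marginal-likelihood algorithm with a Laplace
approximation: starting from (nearly) empty, single basis functions are
added, re-estimated, or deleted, whichever action maximally increases the
approximate log marginal likelihood, until the best available gain falls
below 1e-6 (at most 500 steps). The sequential form was chosen over the
start-full/prune EM form deliberately: the two find different local optima
of the same objective, and the EM form collapses to the empty model on
permutation-null data, which is inconsistent with the guessing-level
behavior the procedure is meant to exhibit (see below). The kernel is a
Gaussian RBF; its width defaults to the median heuristic (median pairwise
training distance), is set once per training set and inherited by
warm-started retrains. The bias basis is never pruned and is effectively
unpenalized (precision 1e-6).

Online decoding initializes from a simulated two-subject pilot set
(120 trials with a distinct seed), then, after each revealed decision,
appends the trial (features + decision) and retrains warm-started from the
previous model's hyperparameters — typically a few milliseconds. Posterior
≥ 0.5 predicts accept; the tie at exactly 0.5 resolves to accept so the
online rule is deterministic.

## Empirical guessing levels

Class imbalance lets trivial strategies beat 50% accuracy, so chance is
estimated empirically: the decision vector is permuted (destroying the
feature–label coherence, retaining class sizes), the classifier is
retrained, and all trials are classified by the retrained model. The
class-wise accuracies — scored against the *actual* decisions, i.e. the
same statistic that is reported for the real experiment, recomputed under
a null training set — are summarized by their geometric mean, which is 0
for any constant classifier. 500 permutations give the mean guessing
level and its 2.5%/97.5% quantiles; an observed accuracy counts as above
chance only if it strictly exceeds the 97.5% quantile.

Three design points deserve note:

* *Scoring.* Accuracies of the permuted-retrained classifier could be
  taken against either the permuted or the original labels; the choice is
  consequential. Scoring against the original decisions
  is the exchangeability-correct null for the reported statistic and is
  implemented; it also reproduces the characteristic above-50% guessing
  levels of imbalanced data (a permutation of an imbalanced vector agrees
  with the original above chance). Scoring against the permuted labels
  instead measures training fit and is inflated by chance-fitting
  (~+8 points on balanced nulls in our measurements).
* *Ties.* A fully-pruned RVM on balanced labels has bias exactly 0 and
  posterior exactly 0.5 everywhere. Inside the estimator such maximally
  uncertain predictions receive half credit per class (a deterministic
  convention, like tie handling in rank statistics); mapping them through
  the online accept-tie rule would score an uninformative model as a
  *constant* one (geometric mean 0) and bias the null mean downward by
  1–2 points.
* *Residual bias.* Even so, the mean guessing level on balanced null data
  sits slightly below 50% (measured ≈47–49.5% at n = 60): the geometric
  mean is concave, so prediction-split variability across permutations
  costs E[sqrt(acc_a · acc_r)] a term of order the split variance. This
  is a property of the summary statistic itself, not of the classifier.
  The quantile-based significance rule is unaffected.

A resubstitution-free variant (`method = "loocv"`) and a pilot-anchored
variant (`prior_x`/`prior_y`, mirroring an online classifier whose
training set always contains the label-fixed pilot data) are exposed for
sensitivity analyses; both are biased low on balanced nulls and are not
the default.

## Retraining benefit

To quantify what continuous retraining buys, paired decodes of the same
sessions (retrained vs frozen initial model) are compared in a sliding
window of six trials, counting extra correct predictions summed over
sessions (with seven sessions, 42 predictions per window). The package's
simulated analogue plants a subject shift: test subjects carry a
nonspecific offer response (default AI/LPFC +0.6) absent from the pilot
population, which displaces all t-features and degrades the frozen
decision boundary while retraining adapts within the session. The claim
tested is directional (mean retrained accuracy exceeds frozen accuracy at
α = 0.05 across 50 sessions), not a specific percentage-point gain.

## Whole-brain analyses

The offline path operates on trial-average samples: per-subject voxelwise
z-scored volumes, averaged over post-offer scans 2–4 (the window in which
decisions are internally made but the response mapping is still unknown).
The whole-brain simulator generates these samples directly — spherical
clusters with choice-, category- or value-coded amplitudes plus iid
Gaussian voxel noise on a configurable MNI-lattice grid — rather than full
4D series; preprocessing primitives (9 mm Gaussian smoothing, 0.01 Hz
DCT high-pass, detrending, z-scoring) are implemented and tested
separately. Simulated cluster geometry defaults to tabulated
discriminating-volume centers so that map recovery has ground truth.

Classification is a linear soft-margin SVM (LIBSVM via e1071; C = 1 by
default and exposed in every signature), preceded
by correlation feature selection: voxels with |Pearson r| with the labels
at or below 0.15 are excluded, computed on training samples only —
leave-one-out folds re-select inside every fold, and a constructed
counterexample in the test suite verifies the held-out sample cannot leak
into selection. Degenerate folds (single-class training) are skipped with
a warning and reported through the effective n.

The choice-versus-value dissociation uses 200 subsets balanced over the
four choice × value cells (value categories: high = 50:50, 65:35, 70:30;
low = 80:20, 90:10 — split at the behavioral border), each subset sized at
four times the smallest cell, and compares leave-one-out accuracies of
the two labelings of identical samples. Adjacent-offer discrimination
draws 42 trials per split rate, 200 times per adjacent pair; a
category-coded signal must peak at 70:30 vs 80:20, a value-coded signal
must not.

## Weight maps and cluster inference

The trained linear SVM's primal weights (recovered from the dual,
`w = Σ αᵢ yᵢ xᵢ`) are scattered back to voxel space (unselected voxels 0)
and scaled to unit Euclidean norm; a voxel's absolute weight measures its
importance. Significance is permutation-based: the entire pipeline
(selection + training + back-projection) is rerun under label
permutations and each voxel's p-value is the add-one probability
`(1 + #{perm |w| ≥ observed}) / (n_perm + 1)` — never 0, with 1000
permutations by default. The per-voxel test uses |w| rather than signed
weights, matching the importance interpretation (either sign marks an
informative voxel). Voxels with p < 0.05 (uncorrected) are grouped
by 26-connectivity (configurable to 6/18) and clusters below 300 mm³
(12 voxels at 3 mm) are discarded; surviving clusters are tabulated with
center of mass in MNI mm, volume and peak |weight|.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline at sizes chosen to keep a
complete run in the tens of minutes on one CPU: 50 decoded sessions for
the power and retraining analyses (one pilot set shared across sessions,
as a single pilot data set would be in practice), 500-permutation guessing levels throughout, 199
permutations for weight-map inference on reduced grids (~1.2k–17k
voxels), and for the dissociation analyses a strongly scaled-down
125-voxel grid with 200 balanced subsets and 100 adjacent-pair
repetitions. These are analysis sizes, not limits of the implementation;
every count is an explicit argument.

## Known limitations

* The generative model is deliberately favorable: effects are stationary,
  spherical and uncorrupted by motion or physiological noise; absolute
  accuracies obtained here do not transfer to real recordings.
* The RVM marginal likelihood is a Laplace approximation, and the
  sequential search is greedy; different (legitimate) optima exist.
* The empirical guessing level inherits the concavity bias of the
  geometric-mean summary discussed above.
* Real-time behavior is simulated: per-trial retraining durations are
  logged, but no scheduling deadlines are enforced.
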