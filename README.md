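# ugdecode

Predicting a responder's accept/reject decisions in the ultimatum game
from BOLD fMRI activity *before* the decision is revealed — as a fully
simulated, tested pipeline.

In the repeated ultimatum game a responder sees an offer splitting a
3-euro stake (6×50:50, 8×65:35, 12×70:30, 21×80:20, 13×90:10 per 60-trial
session, 22 s per trial) and accepts or rejects it a few seconds later.
`ugdecode` implements the real-time decoding stack for this paradigm
against synthetic sessions with known ground truth:

* **Paradigm + BOLD simulation** — seeded offer schedules, a logistic
  responder (acceptance cliff between 70:30 and 80:20), and 4D sessions in
  which anterior insula (AI) and lateral prefrontal cortex (LPFC) activate
  before rejections and occipital cortex (OC) before acceptances, with
  double-gamma hemodynamics, linear drift and AR(1) noise.
* **Online decoding** — per trial, the pooled ROI series of the first
  10 s after the offer are reduced to three t-values (active scans 3–5
  vs baseline scans 1–2, pooled variance, 3 df) that feed a relevance
  vector machine: sparse Bayesian kernel logistic regression trained by
  the sequential fast marginal-likelihood algorithm, retrained after
  every revealed trial (warm-started, milliseconds per update), with the
  prediction committed before the response phase.
* **Validation** — permutation-based empirical guessing levels
  (geometric mean of class-wise accuracies of permuted-retrained
  classifiers, 500 permutations, strict 97.5%-quantile rule) and the
  sliding-window retraining-benefit analysis.
* **Whole-brain analyses** — correlation feature selection (|r| > 0.15),
  linear SVM (LIBSVM, C = 1), leave-one-trial-out and
  leave-one-subject-out cross-validation, 200 balanced choice×value
  subsets, adjacent-offer discrimination.
* **Weight maps** — unit-norm back-projection of SVM weights,
  1000-permutation per-voxel p-values (add-one convention), 26-connected
  cluster filtering at 300 mm³, and recovery of clusters planted at
  tabulated MNI centers.

## Worked example

```r
library(ugdecode)

# pilot data stand-in (2 subjects, 120 trials) and initial classifier
cfg   <- sim_config(noise_scope = "roi")
pilot <- simulate_pilot_set(config = cfg, seed = 100)
model <- rvm_train(pilot$x, pilot$y)

# one synthetic session: schedule, decisions, 660-scan BOLD run
sched <- simulate_decisions(build_offer_schedule(seed = 1), seed = 51)
sess  <- simulate_session(cfg, sched, seed = 901)

# decode it trial by trial, retraining after every revealed decision
log <- run_online_session(sess, model, pilot)
session_accuracy(log)
#> [1] 95

# is that above the empirical guessing level of this session?
feats <- cbind(LPFC = log$t_lpfc, AI = log$t_ai, OC = log$t_oc)
est <- empirical_guessing_level(feats, log$truth, n_perm = 500, seed = 1)
est
#> Empirical guessing level: mean 32.9% [0.0%, 90.3%] (500 permutations)
exceeds_guessing(session_accuracy(log), est)
#> [1] TRUE
```

The session accuracy (95% here, with the default strong embedded
effects) is the percentage of trials whose decision was predicted
correctly before the response screen. The guessing estimate summarizes
what the same classifier achieves after label permutations destroy the
feature–decision coherence; only an accuracy strictly above its 97.5%
quantile counts as real decoding.

A thin command-line front end wraps the same functions
(`inst/cli/ugdecode.R`): `simulate`, `run-online`, `guessing`,
`wholebrain`, `maps`, `report`.

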