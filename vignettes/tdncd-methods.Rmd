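---
title: "Quantifying dynamic functional-connectivity reconfiguration with tdNCD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic functional-connectivity reconfiguration with tdNCD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Resting-state fMRI functional connectivity (FC) is usually summarised as a
single correlation matrix over the whole scan. That static summary hides
how a region's pattern of connections re-organises over the scan — the
network *reconfiguration* that dynamic-FC analyses target. This package
implements a region-level reconfiguration statistic, the **time-distance
nodal connectivity diversity (tdNCD)**, together with the multi-site group
comparison and leave-one-site-out classification machinery needed to use it
as a disease marker in pooled cohorts (the motivating application is
Alzheimer's disease versus normal controls, with MCI as an intermediate
group).

## The statistic

Inputs are preprocessed regional time series: a `T × R` matrix per subject
(`T` frames at repetition time TR, `R` atlas regions). Three steps:

1. **Sliding-window dynamic FC.** Pearson correlation matrices are computed
   in rectangular windows of `W` seconds advancing by `s` seconds
   (defaults `W = 100`, `s = 10`, TR = 2 s, so 50-frame windows advancing
   by 5 frames; a 170-frame scan yields 25 windows). Trailing frames that
   do not fill a window are dropped.

2. **Window-pair nodal connectivity diversity.** For region `n` and windows
   `i, j`, the connectivity profile of `n` (its row of the window FC matrix
   with the self-connection removed) is compared across windows:

   `dNCD_n(i, j) = 1 − |cor(dFC_i[n, −n], dFC_j[n, −n])|`.

   The absolute value is deliberate: a profile that flips sign wholesale is
   treated as preserved, not reconfigured. Values live in `[0, 1]`.

3. **Time-distance profile.** For each lag `d` (in window steps),

   `tdNCD_n(d) = mean over i of dNCD_n(i, i + d)`,

   an average of `T_w − d` window pairs, where `T_w` is the window count.
   With 25 windows this yields 24 time distances (10 s … 240 s), one
   reconfiguration curve per region.

The same row distance applied to two *static* FC matrices (two conditions,
two mental states) is exposed as `ncd()`; no separate code path exists
because the operations are identical.

Numerical conventions worth stating: the seconds-to-frames conversion
rounds to the nearest frame; window counts follow
`floor((T − W_f)/s_f) + 1`; self-connections are removed from both profiles
before correlating (a shared constant distorts a Pearson correlation and
carries no information); constant profiles or constant ROI columns are hard
errors rather than silent `NaN`s, because preprocessed fMRI should never
contain them and silence hides upstream bugs.

## Multi-site group comparison

Scanner and protocol differences make naive pooling across sites unsafe, so
the group analysis is a per-site test followed by a meta-analytic
combination:

* At each site, a two-sided two-sample t-test (Student, pooled variance;
  Welch available) compares NC and AD for every feature (each region ×
  distance cell, or each FC edge). Sites with fewer than 2 subjects per
  group are dropped with a warning.
* Per-site p-values become signed z-scores,
  `z_i = sign(t_i) · Φ⁻¹(1 − p_i/2)`, and are pooled with the weighted
  Liptak–Stouffer statistic `z = Σ w_i z_i / sqrt(Σ w_i²)` with
  `w_i = sqrt(n_i)` (site sample size). The combined two-sided p is
  `2(1 − Φ(|z|))`. Signing by the effect direction is essential: an
  unsigned combination would let opposite-direction effects reinforce each
  other, and mapping `p = Φ(z)` would make stronger evidence yield larger
  p-values.
* Bonferroni correction: the tdNCD family corrects across the 24 time
  distances within a region (per-test threshold `0.05/24 ≈ 0.0021`), and a
  region is flagged when any distance survives. The FC comparison corrects
  with a family size equal to the number of regions (264 under the default
  parcellation) — not the edge count — and a region is flagged when at
  least one incident edge survives. The FC family size is a convention
  adopted deliberately for comparability; with ~35k edges it is far more
  permissive than a full edge-wise correction, and `meta_significance()`
  lets you override `family_size` if you want the stricter variant.

A genuine property of the weighted Stouffer statistic that users sometimes
find surprising: adding an *agreeing but weak* site can increase the
combined p, because the weight enters the denominator whether or not the
site contributes evidence. The combination is, however, strictly monotone
in each site's p-value, and invariant to rescaling all sample sizes by a
common factor.

## Classification framework

Feature tables combine static FC edges (upper triangle, `R(R−1)/2`
columns), tdNCD cells (`R × D` columns) and optionally windowed dFC edges.
Because features vastly outnumber subjects, a univariate two-sample t-test
filter (NC vs AD, training data only) keeps features below a per-kind
threshold — 0.001 for sFC, 1e−5 for dFC, 0.05 for tdNCD — chosen so the
surviving count is of the same order as the subject count.

Five model families are available: a compact 4-layer fully connected
network (`fcnet`: input → 64 → 32 → softmax, rectified-linear hidden
units, full-batch Adam) and four classical baselines (linear SVM, KNN with
`k = 5`, L2-regularised logistic regression, LDA). Only the network is
tuned: its two hyperparameters (training passes and Adam learning rate)
are grid-searched; hidden widths are fixed — with cohorts of a few hundred
subjects a deeper or wider search invites overfitting of the model
*selection* itself.

Evaluation is **nested leave-one-site-out**: each site in turn is held out
as the test set; within the remaining sites, each in turn serves as
validation to pick hyperparameters by mean validation accuracy (ties break
toward the smaller learning rate, then fewer passes); the winner is refit
on all non-test sites. Feature selection and per-column z-scoring are
fitted inside the training rows of every split — never on held-out data —
and the package carries a "leakage canary" validation experiment
(`leakage_canary()`) in which a feature equal to the held-out-site
indicator must not lift accuracy above chance.

Decision scores are the predicted AD-class probability (for the SVM, a
logistic transform of the one-vs-one margins; for the three-class task,
the AD component of the softmax/posterior vector). For the two-class task
the refit model also scores the held-out site's MCI subjects, so decision
scores can be correlated with MMSE over the pooled AD + MCI test subjects
(`decision_mmse_correlation()`). Model families are compared with paired
two-sided t-tests across per-fold metrics; a constant nonzero fold
difference makes the paired t degenerate and is flagged rather than
silently returned as significant.

Metrics are reported in percent: accuracy, sensitivity (recall of AD),
specificity, and F1 with AD positive; the three-class task reports
unweighted macro averages (the macro convention is a documented choice).

## The synthetic cohort generator

No public dataset accompanies the method at desk scale, so the package
ships a generator whose *ground truth is the quantity the statistic
measures*. Each subject is a first-order Markov chain over `S` latent
connectivity states (default 3), holding each state with per-group dwell
probability (default 0.95 per 2 s frame, i.e. mean state runs of ~40 s,
within the range dynamic-FC studies report). Each state is a factor model:
one latent factor per network plus a global factor, with one network
dominantly coupled per state. Factor construction keeps every state
covariance positive definite by design — important, because an earlier
block-matrix draft needed whole-matrix eigenvalue repair that bled group
differences into supposedly unaffected regions.

Planted effects tune how much an affected region's *profile shape* varies
across states, which is exactly what tdNCD measures, while leaving the
state-average profile in place:

* direction +1 re-routes the region's loadings toward each state's
  dominant network with weight `min(δ, 1)` — large state-to-state shape
  change, higher tdNCD;
* direction −1 shrinks the region's loading contrast across states by
  `1 − δ` (floored at 0) — a frozen profile, lower tdNCD.

Defaults plant 5 evenly spaced regions (3 positive, 2 negative) with
`δ = 1` in AD and `δ = 0.5` in MCI. Sites differ in additive white-noise
SD (0.3–0.6) and global gain (0.9–1.1). MMSE is drawn per group from
truncated normals with means and spreads typical of these diagnostic
groups (NC 28.52 ± 1.64, MCI 25.14 ± 3.39, AD 16.56 ± 6.02). The full-size
default reproduces a 7-site cohort of 809 subjects (257/257/295
NC/MCI/AD). One master seed spawns an independent stream per (site, group,
subject index), so adding subjects to one site never perturbs another
subject's data.

What the generator does *not* emulate: hemodynamic filtering,
autocorrelated physiological noise spectra, motion artefacts, spatial maps,
or realistic inter-regional anatomy. Passing tests therefore demonstrate
the pipeline's statistical behaviour under a controlled reconfiguration
model, not performance on real fMRI.

### Switching rate and window geometry

A point that shapes the validation experiments: with 100 s windows stepped
by 10 s, windows at lag 1 share 90% of their frames, so tdNCD at short
lags is dominated by shared-sample correlation and barely responds to the
switching rate. The switching signal appears at lags of at least one
window length, and its dependence on dwell time is a hump: reconfiguration
is maximal when state runs are comparable to the window (~dwell 0.99 per
frame), and falls off both for near-static dynamics and for switching so
fast that every window averages over all states. The dwell-sensitivity
property tests therefore compare dwell 0.999 vs 0.99 at lags ≥ 100 s,
the monotone regime.

### Calibration of the meta-analysis, and why replication is needed

Under a zero-effect cohort the pipeline's combined p-values are calibrated:
pooled over independent replicate cohorts, their distribution is uniform
and the p < 0.05 rate matches 0.05. But the 960 region × distance features
of one 40-region cohort are far from independent — every region's 24
distances are averages over the *same* 25 window profiles — so the
effective number of independent tests is an order of magnitude smaller
than the feature count, and the false-positive rate of a single cohort
fluctuates far more than the binomial formula at 960 features suggests. The calibration experiment (`null_calibration()`)
consequently runs 10 replicate zero-effect cohorts (single connectivity
state, so group assignment is pure labelling; site noise and gain
differences retained), pools the rate, and reports the Monte-Carlo SE
estimated *from the replicates*. The acceptance checks compare the pooled
rate against 0.05 at twice that SE, and the pooled p-value distribution
against uniformity with a KS test at the 1% critical value of the
960-feature family.

### Problem sizes used by the validation experiments

Chosen to make each experiment's conclusion statistically meaningful:
null calibration uses 10 replicate cohorts of 7 sites × (40 NC + 40 AD)
at 40 regions (larger groups keep the t→normal approximation error, which
the 7-site combination amplifies, from biasing the combined p-values); parameter recovery uses 10 replicate cohorts of 7 × (25 + 25) with
5 of 40 regions planted at δ = 1, scoring regions by their best combined
evidence across distances, averaging each region's evidence over the
replicates (the planted set is fixed) and summarising the replicated
experiment with one Mann–Whitney AUC — per-replicate AUCs are also
reported, but a single 50-subject-per-site cohort ranks the two
suppressed-reconfiguration regions (whose effect saturates at δ = 1) with
considerable noise; the
classification positive control uses the same cohort size with the
logistic-regression baseline against a matched δ = 0 control; the leakage
canary uses 7 × 30 subjects with site-indicator plus noise features.

## Known limitations

* The rectangular window and its 100 s length bound the temporal
  resolution; lags shorter than the window are dominated by shared frames.
* The absolute value in the profile distance means wholesale
  anticorrelation of a profile counts as stability. This follows the
  statistic's definition; users probing sign-flipping dynamics need a
  different distance.
* The FC-edge Bonferroni family size (number of regions, not edges) is a
  comparability convention, not an error-rate guarantee over edges.
* Pooled-variance t-tests assume comparable within-site group variances;
  Welch's variant is available via `var_equal = FALSE`.
* The generator's Gaussian, white-noise observation model understates the
  heavy tails and autocorrelation of real fMRI noise; effect sizes
  calibrated on it do not transfer to real data.
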