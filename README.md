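# tdncd

Region-level quantification of dynamic functional-connectivity
reconfiguration in resting-state fMRI, with multi-site meta-analytic group
comparison and leave-one-site-out classification. Built for researchers
studying network dynamics in pooled clinical cohorts — the motivating
application is separating Alzheimer's disease (AD) from normal controls
(NC), with mild cognitive impairment (MCI) as an intermediate group.

## The statistic

Static functional connectivity (one Pearson correlation matrix per scan)
hides how a region's connection pattern re-organises during the scan. The
**time-distance nodal connectivity diversity (tdNCD)** measures that
reconfiguration per region and per time scale:

1. Sliding-window dynamic FC: correlation matrices `dFC_i` in rectangular
   windows of `W = 100` s stepping by `s = 10` s (TR = 2 s → 50-frame
   windows, 5-frame step; a 170-frame scan gives 25 windows).
2. Window-pair nodal diversity for region *n*:

   ```
   dNCD_n(i, j) = 1 − | cor( dFC_i[n, −n], dFC_j[n, −n] ) |
   ```

   (the region's connectivity profile across windows, self-connection
   removed; 0 = preserved shape, 1 = full reconfiguration).
3. Averaging over all window pairs at lag `d` gives the time-distance
   profile, one curve per region:

   ```
   tdNCD_n(d) = mean_{i} dNCD_n(i, i + d),   d = 1 … T_w − 1
   ```

   With 25 windows: 24 time distances, 10 s to 240 s.

Group inference pools per-site two-sample t-tests with the weighted
Liptak–Stouffer meta-analysis, `z = Σ w_i z_i / sqrt(Σ w_i²)` with
`w_i = sqrt(n_i)` and signed `z_i = sign(t_i) Φ⁻¹(1 − p_i/2)`, then applies
Bonferroni correction over the 24 distances (per-test threshold
0.05/24 ≈ 0.0021); a region is flagged when any distance survives.
Classification (a compact 4-layer fully connected network plus SVM / KNN /
logistic-regression / LDA baselines, t-test feature selection) is
evaluated with nested leave-one-site-out cross-validation.

A Markov state-switching factor-model simulator generates multi-site
cohorts with controllable ground-truth reconfiguration effects, so the
entire pipeline is testable without any data download. See the methods
vignette (`vignettes/tdncd-methods.Rmd`) for the model, its assumptions
and the design decisions.

## Worked example

Simulate a 7-site cohort with a planted reconfiguration effect (5 of 40
regions, effect size δ = 1 in AD), compute tdNCD for every subject, and
run the meta-analytic group comparison:

```r
library(tdncd)

spec <- synthetic_spec(R = 40, n_sites = 7,
                       group_sizes = matrix(c(12, 0, 12), 7, 3, byrow = TRUE),
                       effect_delta = c(NC = 0, MCI = 0.5, AD = 1), seed = 7)
cohort <- generate_cohort(spec)
cohort
#> synthetic cohort: 168 subjects over 7 sites (AD = 84, NC = 84)

stack <- compute_dfc(cohort$timeseries[[1]])
stack
#> dFC stack: 25 windows x 40 x 40 ROIs (window 50 frames, step 5)
compute_tdncd(stack)
#> tdNCD profile: 40 ROIs x 24 time distances (10 .. 240 s)
#>   grand mean 0.380 (0 = stable, 1 = full reconfiguration)

profiles <- cohort_profiles(cohort, kinds = "tdncd")
feats <- tdncd_features(profiles$tdncd)
meta <- stouffer_combine(sitewise_ttest(feats, profiles$manifest))
sig <- meta_significance(meta, tdncd_annotation(40, 24), family = "tdncd_24")
sig
#> meta-analysis (tdncd_24): 960 features, threshold p < 0.002083 (alpha 0.05 / 24)
#>   57 significant features; 3 of 40 regions flagged
sig$rois$roi[sig$rois$flagged]
#> [1]  1 11 20
cohort$ground_truth$affected_rois
#> [1]  1 11 20 30 40
```

At this deliberately modest sample size (12 + 12 per site) the comparison
recovers the three planted regions whose effect direction *amplifies*
reconfiguration, with no false flags; the two suppressed-reconfiguration
regions carry a weaker signature and need larger groups (the validation
experiments in `planted_recovery()` use 25 per group over 10 replicate
cohorts). Reading the numbers: each of the 960 region × distance cells got
a combined z/p across the 7 sites, 57 cells fell below the Bonferroni
threshold 0.0021, and those cells concentrate in 3 regions.

Classification on the same kind of cohort:

```r
X <- build_feature_table(profiles, "tdncd_roi_distance")
report <- nested_loso(X, profiles$manifest,
                      classifier_spec("lr", seed = 1), task = "nc_vs_ad")
```

A command-line wrapper over the same functions is installed at
`inst/cli/tdncd` with subcommands `simulate`, `dfc`, `tdncd`,
`group-stats`, `classify`, `report`.

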