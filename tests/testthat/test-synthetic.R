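test_that("simulated subjects honor the acquisition geometry", {
  spec <- synthetic_spec(R = 20, group_sizes = matrix(1, 7, 3), seed = 2)
  ts <- simulate_subject(spec, 3, "AD", seed = 99)
  expect_identical(dim(ts$values), c(170L, 20L))
  expect_true(all(is.finite(ts$values)))
  expect_true(all(apply(ts$values, 2, sd) > 0))
  expect_identical(ts$site_id, "site3")
  expect_true(ts$mmse >= 0 && ts$mmse <= 30)
})

test_that("state covariances are valid correlation matrices for all groups", {
  spec <- synthetic_spec(R = 24, group_sizes = matrix(1, 7, 3),
                         effect_delta = c(NC = 0, MCI = 0.5, AD = 1))
  for (g in c("NC", "MCI", "AD")) {
    for (Sig in tdncd:::state_covariances(spec, g)) {
      expect_equal(diag(Sig), rep(1, 24))
      expect_equal(Sig, t(Sig))
      ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("cohort generation is reproducible from spec and seed", {
  spec <- synthetic_spec(R = 10, n_sites = 2,
                         group_sizes = matrix(2, 2, 3), seed = 31)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  for (id in names(c1$timeseries))
    expect_identical(c1$timeseries[[id]]$values, c2$timeseries[[id]]$values)
})

test_that("per-subject streams are independent of cohort composition", {
  base <- synthetic_spec(R = 10, n_sites = 2,
                         group_sizes = matrix(2, 2, 3), seed = 7)
  bigger <- synthetic_spec(R = 10, n_sites = 2,
                           group_sizes = matrix(c(5, 2, 2, 2, 2, 2), 2, 3),
                           seed = 7)
  c1 <- generate_cohort(base)
  c2 <- generate_cohort(bigger)
  shared <- intersect(names(c1$timeseries), names(c2$timeseries))
  expect_gt(length(shared), 0)
  for (id in shared)
    expect_identical(c1$timeseries[[id]]$values, c2$timeseries[[id]]$values)
})

test_that("an empty size table yields an empty cohort without error", {
  spec <- synthetic_spec(R = 10, n_sites = 2,
                         group_sizes = matrix(0, 2, 3), seed = 1)
  coh <- generate_cohort(spec)
  expect_identical(nrow(coh$manifest), 0L)
})

test_that("written cohorts round-trip and refuse silent overwrites", {
  spec <- synthetic_spec(R = 6, n_sites = 2,
                         group_sizes = matrix(1, 2, 3), seed = 13)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  coh <- generate_cohort(spec, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.yaml")))
  id <- coh$manifest$subject_id[1]
  back <- read_timeseries(coh$manifest$path[1])
  mem <- generate_cohort(spec)$timeseries[[id]]
  expect_equal(back$values, mem$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(generate_cohort(spec, out_dir = out), "not empty")
  expect_silent(generate_cohort(spec, out_dir = out, overwrite = TRUE))
})

test_that("manifest-only generation matches the full run's manifest", {
  spec <- synthetic_spec(R = 8, n_sites = 2,
                         group_sizes = matrix(2, 2, 3), seed = 17)
  m_only <- generate_cohort(spec, manifest_only = TRUE)
  full <- generate_cohort(spec)
  expect_identical(m_only$manifest[c("subject_id", "site_id", "diagnosis",
                                     "mmse")],
                   full$manifest[c("subject_id", "site_id", "diagnosis",
                                   "mmse")])
  expect_null(m_only$timeseries)
})

# Switching-rate sensitivity lives at time distances beyond the window
# length: windows closer than one window length share most of their frames,
# and within-window averaging suppresses the state signal. The monotone
# regime is slow switching (state runs comparable to or longer than the
# window); at very fast switching every window sees the state average and
# reconfiguration falls again.
mean_tdncd_beyond_window <- function(dwell, seed, n_sub = 4) {
  spec <- synthetic_spec(R = 12, n_sites = 1,
                         group_sizes = matrix(c(n_sub, 0, 0), 1, 3),
                         dwell = c(NC = dwell, MCI = dwell, AD = dwell),
                         effect_delta = c(NC = 0, MCI = 0, AD = 0),
                         seed = seed)
  coh <- generate_cohort(spec)
  mean(sapply(coh$timeseries, function(ts)
    mean(compute_tdncd(compute_dfc(ts))$matrix[, 10:15])))
}

test_that("more state switching raises reconfiguration at non-overlapping lags", {
  # paired replicates: the same subject stream evaluated under two dwell
  # probabilities (common random numbers), 20 replicate seeds
  diffs <- sapply(1:20, function(rep)
    mean_tdncd_beyond_window(0.99, 1000 + rep, n_sub = 8) -
      mean_tdncd_beyond_window(0.999, 1000 + rep, n_sub = 8))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("dwell-time contrast between groups shifts tdNCD directionally", {
  # two groups differing only in dwell probability, paired across seeds
  diffs <- sapply(1:10, function(rep) {
    spec <- synthetic_spec(R = 12, n_sites = 1,
                           group_sizes = matrix(c(3, 0, 3), 1, 3),
                           dwell = c(NC = 0.999, MCI = 0.99, AD = 0.99),
                           effect_delta = c(NC = 0, MCI = 0, AD = 0),
                           seed = 3000 + rep)
    coh <- generate_cohort(spec)
    td <- sapply(coh$timeseries, function(ts)
      mean(compute_tdncd(compute_dfc(ts))$matrix[, 10:15]))
    diag <- coh$manifest$diagnosis
    mean(td[diag == "AD"]) - mean(td[diag == "NC"])
  })
  expect_gt(mean(diffs), 0)
})

test_that("site parameters leave a detectable site signature", {
  spec <- synthetic_spec(R = 10, n_sites = 2, n_states = 1,
                         group_sizes = matrix(c(10, 0, 0), 2, 3,
                                              byrow = TRUE),
                         site_noise_sd = c(0.2, 0.8),
                         site_gain = c(0.9, 1.1),
                         effect_delta = c(NC = 0, MCI = 0, AD = 0),
                         seed = 47)
  coh <- generate_cohort(spec)
  prof <- cohort_profiles(coh, kinds = "tdncd")
  feats <- tdncd_features(prof$tdncd)
  site <- prof$manifest$site_id
  p <- t.test(rowMeans(feats) ~ site)$p.value
  expect_lt(p, 0.01)
})
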