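test_that("metrics match hand-computed confusion tables", {
  perfect <- compute_metrics(c("AD", "AD", "NC"), c("AD", "AD", "NC"))
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  m <- compute_metrics(c("AD", "AD", "NC", "NC"),
                       c("AD", "NC", "NC", "NC"))
  expect_equal(unname(m), c(75, 50, 100, 200 / 3), tolerance = 1e-9)
})

test_that("macro metrics sit at chance for uniform random predictions", {
  set.seed(55)
  n <- 3000
  truth <- sample(c("NC", "MCI", "AD"), n, replace = TRUE)
  pred <- sample(c("NC", "MCI", "AD"), n, replace = TRUE)
  m <- compute_metrics(truth, pred, positive_class = "macro")
  se <- 100 * 2 / sqrt(n)
  expect_lt(abs(m["F1"] - 100 / 3), 2 * se)
  expect_lt(abs(m["ACC"] - 100 / 3), 2 * se)
  expect_lt(abs(m["SPE"] - 200 / 3), 2 * se)
})

test_that("classes absent from the truth are dropped with a warning", {
  expect_warning(m <- compute_metrics(c("NC", "NC", "AD", "AD"),
                                      c("NC", "MCI", "AD", "AD"),
                                      positive_class = "macro"),
                 "absent from truth")
  expect_true(all(is.finite(m)))
})

test_that("a perfectly separating feature yields perfect folds", {
  coh <- toy_classification_cohort(n_sites = 4, n_per_group = 6,
                                   separation = 8, seed = 3)
  spec <- classifier_spec("lda", seed = 1)
  rep1 <- nested_loso(coh$features, coh$manifest, spec, task = "nc_vs_ad")
  expect_identical(nrow(rep1$folds), 4L)  # one fold per site
  expect_true(all(rep1$folds$status == "ok"))
  expect_equal(rep1$folds$ACC, rep(100, 4))
  expect_equal(rep1$folds$SEN, rep(100, 4))
  expect_equal(rep1$folds$SPE, rep(100, 4))
  expect_equal(rep1$folds$F1, rep(100, 4))
})

test_that("evaluation is deterministic for the same seed and inputs", {
  coh <- toy_classification_cohort(n_sites = 3, n_per_group = 8,
                                   separation = 1.5, seed = 13)
  for (m in c("fcnet", "svm", "knn", "lr", "lda")) {
    spec <- classifier_spec(m, seed = 5,
                            grid = list(learning_rate = c(1e-2, 1e-3),
                                        epochs = c(20L, 40L)))
    r1 <- nested_loso(coh$features, coh$manifest, spec)
    r2 <- nested_loso(coh$features, coh$manifest, spec)
    expect_identical(r1$folds, r2$folds)
    expect_identical(r1$scores, r2$scores)
  }
})

test_that("three-class evaluation reports macro metrics per fold", {
  coh <- toy_classification_cohort(n_sites = 3, n_per_group = 7,
                                   separation = 6, seed = 23,
                                   with_mci = TRUE)
  spec <- classifier_spec("lda", seed = 2)
  rep3 <- nested_loso(coh$features, coh$manifest, spec, task = "nc_mci_ad")
  expect_identical(nrow(rep3$folds), 3L)
  expect_true(all(rep3$folds$ACC > 50))
  expect_true(all(rep3$scores$diagnosis %in% c("NC", "MCI", "AD")))
})

test_that("MCI subjects of the held-out site receive decision scores", {
  coh <- toy_classification_cohort(n_sites = 3, n_per_group = 6,
                                   separation = 4, seed = 31,
                                   with_mci = TRUE)
  spec <- classifier_spec("lr", seed = 4)
  rep1 <- nested_loso(coh$features, coh$manifest, spec, task = "nc_vs_ad")
  n_mci <- sum(coh$manifest$diagnosis == "MCI")
  expect_identical(sum(rep1$scores$diagnosis == "MCI"), n_mci)
  expect_true(all(rep1$scores$score >= 0 & rep1$scores$score <= 1))
})

test_that("a fold missing a required class is reported and skipped", {
  coh <- toy_classification_cohort(n_sites = 4, n_per_group = 6,
                                   separation = 8, seed = 41)
  man <- coh$manifest
  drop <- man$site_id == "site2" & man$diagnosis == "AD"
  man <- man[!drop, ]
  X <- coh$features[man$subject_id, ]
  attr(X, "kind") <- attr(coh$features, "kind")
  spec <- classifier_spec("lda", seed = 1)
  expect_warning(rep1 <- nested_loso(X, man, spec), "lacks class")
  expect_identical(sum(rep1$folds$status == "missing"), 1L)
  expect_identical(sum(rep1$folds$status == "ok"), 3L)
})

test_that("decision scores anticorrelate with cognition by construction", {
  sc <- data.frame(subject_id = sprintf("s%d", 1:30), site = "site1",
                   diagnosis = rep(c("AD", "MCI"), 15),
                   mmse = round(seq(5, 29, length.out = 30)))
  sc$score <- (30 - sc$mmse) / 30
  r <- decision_mmse_correlation(sc)
  expect_equal(r$R, -1, tolerance = 1e-9)
  expect_identical(r$n, 30L)
})

test_that("scores independent of cognition show no correlation", {
  set.seed(61)
  sc <- data.frame(subject_id = sprintf("s%d", 1:500), site = "site1",
                   diagnosis = "AD", mmse = sample(5:30, 500, TRUE),
                   score = runif(500))
  r <- decision_mmse_correlation(sc)
  expect_lt(abs(r$R), 0.1)
  sc$score <- 0.5
  expect_warning(r0 <- decision_mmse_correlation(sc), "constant")
  expect_true(is.na(r0$R))
})

test_that("paired model comparison handles identical and shifted reports", {
  coh <- toy_classification_cohort(n_sites = 4, n_per_group = 6,
                                   separation = 8, seed = 3)
  spec <- classifier_spec("lda", seed = 1)
  r <- nested_loso(coh$features, coh$manifest, spec)
  same <- compare_models_paired_t(r, r)
  expect_equal(same$t, rep(0, 4))
  expect_equal(same$p, rep(1, 4))
  # constant nonzero difference is degenerate and flagged
  r2 <- r
  r2$folds$ACC <- r$folds$ACC - 3
  cmp <- compare_models_paired_t(r, r2, metrics = "ACC")
  expect_true(cmp$degenerate)
  expect_equal(cmp$p, 0)
  expect_equal(cmp$mean_diff, 3)
  # non-degenerate case agrees with stats::t.test on the fold differences
  r3 <- r
  r3$folds$ACC <- r$folds$ACC - c(2, 4, 3, 5)
  cmp3 <- compare_models_paired_t(r, r3, metrics = "ACC")
  oracle <- t.test(c(2, 4, 3, 5))
  expect_equal(cmp3$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(cmp3$p, oracle$p.value, tolerance = 1e-12)
  # mismatched fold structure is an error
  r4 <- r; r4$folds$site <- rev(r4$folds$site)
  expect_error(compare_models_paired_t(r, r4), "mismatched")
})
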