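make_feature_manifest <- function(values_by_group, site = "siteA") {
  n <- sum(lengths(values_by_group))
  ids <- sprintf("s%03d", seq_len(n))
  man <- data.frame(subject_id = ids,
                    site_id = site,
                    diagnosis = rep(names(values_by_group),
                                    lengths(values_by_group)))
  X <- matrix(unlist(values_by_group), ncol = 1,
              dimnames = list(ids, "f1"))
  list(X = X, manifest = man)
}

test_that("identical groups give t = 0 and p = 1", {
  fx <- make_feature_manifest(list(NC = c(1, 2, 3), AD = c(1, 2, 3)))
  res <- sitewise_ttest(fx$X, fx$manifest)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_two_sided, 1)
  expect_identical(res$effect_sign, 1L)
})

test_that("the pooled t matches the closed-form small-integer example", {
  fx <- make_feature_manifest(list(NC = 1:5, AD = 6:10))
  res <- sitewise_ttest(fx$X, fx$manifest)
  oracle <- brute_pooled_t(1:5, 6:10)
  expect_equal(res$t_stat, -5)
  expect_equal(oracle$t, -5)
  expect_equal(oracle$df, 8)
  expect_equal(res$p_two_sided, oracle$p, tolerance = 1e-12)
  expect_identical(res$effect_sign, -1L)
  expect_identical(res$n_total, 10L)
})

test_that("site-wise t-tests are calibrated under permuted null labels", {
  set.seed(101)
  n <- 40; n_feat <- 2500
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(sprintf("s%03d", 1:n), NULL))
  man <- data.frame(subject_id = rownames(X), site_id = "siteA",
                    diagnosis = sample(rep(c("NC", "AD"), each = n / 2)))
  res <- sitewise_ttest(X, man)
  rate <- mean(res$p_two_sided < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n_feat)
  expect_lt(abs(rate - 0.05), 2 * mc_se + 1e-12)
})

test_that("undersized sites are skipped with a warning, not fatal", {
  fx <- make_feature_manifest(list(NC = 1:4, AD = c(2, 3, 4, 6)))
  tiny <- make_feature_manifest(list(NC = 1, AD = c(2, 3)), site = "siteB")
  X <- rbind(fx$X, tiny$X)
  rownames(X) <- c(fx$manifest$subject_id,
                   paste0("b", tiny$manifest$subject_id))
  man <- rbind(fx$manifest,
               transform(tiny$manifest,
                         subject_id = paste0("b", subject_id)))
  expect_warning(res <- sitewise_ttest(X, man), "siteB skipped")
  expect_identical(unique(res$site_id), "siteA")
})

test_that("a single site passes through the combination unchanged", {
  res <- data.frame(site_id = "siteA", feature_id = "f1", t_stat = -2.5,
                    p_two_sided = 0.02, effect_sign = -1L,
                    n_group_a = 10L, n_group_b = 12L, n_total = 22L)
  meta <- stouffer_combine(res)
  expect_equal(meta$combined_p, 0.02, tolerance = 1e-12)
  expect_lt(meta$combined_z, 0)
  expect_identical(meta$n_sites_used, 1L)
})

test_that("two agreeing equal-n sites combine to the known z and p", {
  res <- data.frame(site_id = c("a", "b"), feature_id = "f1",
                    t_stat = 2, p_two_sided = 0.05, effect_sign = 1L,
                    n_group_a = 20L, n_group_b = 20L, n_total = 40L)
  meta <- stouffer_combine(res)
  oracle <- brute_stouffer(c(0.05, 0.05), c(1, 1), c(40, 40))
  expect_equal(meta$combined_z, oracle$z, tolerance = 1e-10)
  expect_equal(meta$combined_p, oracle$p, tolerance = 1e-10)
  expect_equal(meta$combined_z, sqrt(2) * qnorm(0.975), tolerance = 1e-9)
  expect_equal(meta$combined_p, 0.0056, tolerance = 1e-2)
})

test_that("opposite effect directions cancel exactly", {
  res <- data.frame(site_id = c("a", "b"), feature_id = "f1",
                    t_stat = c(2, -2), p_two_sided = 0.05,
                    effect_sign = c(1L, -1L),
                    n_group_a = 20L, n_group_b = 20L, n_total = 40L)
  meta <- stouffer_combine(res)
  expect_equal(meta$combined_z, 0)
  expect_equal(meta$combined_p, 1)
})

test_that("combination honors monotonicity, weight and sign symmetries", {
  set.seed(77)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    res <- data.frame(site_id = sprintf("s%d", seq_len(k)),
                      feature_id = "f1",
                      t_stat = 1, p_two_sided = runif(k, 0.001, 0.999),
                      effect_sign = 1L, n_group_a = 10L, n_group_b = 10L,
                      n_total = sample(20:200, k, replace = TRUE))
    base <- stouffer_combine(res)
    # strengthening any one site's evidence strengthens the combination
    sharper <- res
    j <- sample(k, 1)
    sharper$p_two_sided[j] <- res$p_two_sided[j] / 2
    expect_lt(stouffer_combine(sharper)$combined_p,
              base$combined_p + 1e-12)
    # common sample-size factor leaves the combined z unchanged
    scaled <- res; scaled$n_total <- res$n_total * 7L
    expect_equal(stouffer_combine(scaled)$combined_z, base$combined_z,
                 tolerance = 1e-12)
    # flipping all effect signs negates z, keeps p
    flipped <- res; flipped$effect_sign <- -1L
    fl <- stouffer_combine(flipped)
    expect_equal(fl$combined_z, -base$combined_z, tolerance = 1e-12)
    expect_equal(fl$combined_p, base$combined_p, tolerance = 1e-12)
  }
})

test_that("combined p-values are uniform under a simulated global null", {
  set.seed(404)
  n_feat <- 5000; k <- 7
  # site-level two-sided p-values from genuine null t-tests on normal data
  res <- do.call(rbind, lapply(seq_len(k), function(s) {
    z <- matrix(rnorm(n_feat * 2), n_feat, 2)
    t <- (z[, 1] - z[, 2]) / sqrt(2)   # unit-variance null statistic
    data.frame(site_id = sprintf("s%d", s),
               feature_id = sprintf("f%04d", seq_len(n_feat)),
               t_stat = t, p_two_sided = 2 * pnorm(-abs(t)),
               effect_sign = ifelse(t < 0, -1L, 1L),
               n_group_a = 25L, n_group_b = 25L, n_total = 50L)
  }))
  meta <- stouffer_combine(res)
  D <- suppressWarnings(ks.test(meta$combined_p, "punif")$statistic)
  expect_lt(D, 1.628 / sqrt(n_feat))  # 1% critical value
})

test_that("zero p-values are clamped with a warning", {
  res <- data.frame(site_id = "a", feature_id = "f1", t_stat = 50,
                    p_two_sided = 0, effect_sign = 1L,
                    n_group_a = 10L, n_group_b = 10L, n_total = 20L)
  expect_warning(meta <- stouffer_combine(res), "clamped")
  expect_true(is.finite(meta$combined_z))
})

test_that("Bonferroni thresholds match the printed protocol", {
  expect_equal(bonferroni_threshold(0.05, 24), 0.05 / 24)
  expect_equal(round(bonferroni_threshold(0.05, 24), 4), 0.0021)
  expect_equal(bonferroni_threshold(0.05, 264), 0.05 / 264)
})

test_that("significance flags and ROI aggregation work in both families", {
  R <- 6; D <- 3
  ann <- tdncd_annotation(R, D)
  meta <- data.frame(feature_id = ann$feature_id, combined_z = 0,
                     combined_p = 1, n_sites_used = 7L)
  # plant one significant distance in ROI 2
  meta$combined_p[meta$feature_id == "tdNCD_r002_d02"] <- 1e-6
  sig <- meta_significance(meta, ann, family = "tdncd_24", alpha = 0.05,
                           family_size = D)
  expect_identical(sum(sig$features$significant), 1L)
  expect_identical(which(sig$rois$flagged), 2L)
  # all-null table flags nothing
  meta$combined_p <- 1
  sig0 <- meta_significance(meta, ann, family = "tdncd_24",
                            family_size = D)
  expect_identical(sum(sig0$features$significant), 0L)
  expect_identical(sum(sig0$rois$flagged), 0L)
  # FC family: edges incident to a ROI are counted
  eann <- edge_annotation(R)
  emeta <- data.frame(feature_id = eann$feature_id, combined_z = 0,
                      combined_p = 1, n_sites_used = 7L)
  emeta$combined_p[eann$roi_a == 1 & eann$roi_b %in% c(2, 5)] <- 1e-9
  esig <- meta_significance(emeta, eann, family = "fc_264")
  expect_equal(esig$family_size, R)  # family = number of regions
  counts <- esig$rois$n_significant
  expect_identical(counts[1], 2L)
  expect_identical(counts[2], 1L)
  expect_identical(counts[5], 1L)
  expect_identical(which(esig$rois$flagged), c(1L, 2L, 5L))
  expect_error(meta_significance(emeta, eann, family = "bogus"))
})
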