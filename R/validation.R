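# Study-level validation experiments. These drive the full pipeline on
# synthetic cohorts with known ground truth; the test suite and the
# acceptance script call the same functions.

#' Null-calibration experiment for the meta-analytic pipeline
#'
#' Generates replicate zero-effect stationary cohorts (single connectivity
#' state, no planted regions, site noise and gain differences retained),
#' runs the full tdNCD + site-wise t-test + Liptak-Stouffer pipeline on
#' each, and summarises the false-positive behaviour of the combined
#' p-values. Replication matters: the feature family is internally
#' dependent (one region's time distances share windows), so the
#' Monte-Carlo standard error of the false-positive rate must be estimated
#' from independent replicates rather than from the nominal feature count.
#'
#' @param n_replicates Number of independent cohorts (default 10).
#' @param subjects_per_group NC and AD subjects per site (default 40).
#' @param R Number of regions (default 40).
#' @param n_sites Number of sites (default 7).
#' @param seed Master seed.
#' @return A list with per-replicate `rates` (fraction of combined p < 0.05),
#'   `pooled_rate`, `mc_se` (standard error of the pooled rate across
#'   replicates), `ks_d` (Kolmogorov-Smirnov distance of the pooled
#'   p-values from uniform), `n_features`, `n_subjects`.
#' @export
null_calibration <- function(n_replicates = 10, subjects_per_group = 40,
                             R = 40, n_sites = 7, seed = 1) {
  gs <- matrix(c(subjects_per_group, 0, subjects_per_group),
               n_sites, 3, byrow = TRUE)
  rates <- numeric(n_replicates)
  pooled <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- synthetic_spec(R = R, n_states = 1, n_sites = n_sites,
                           group_sizes = gs,
                           effect_delta = c(NC = 0, MCI = 0, AD = 0),
                           seed = derive_seed(seed, r))
    prof <- cohort_profiles(generate_cohort(spec), kinds = "tdncd")
    meta <- stouffer_combine(sitewise_ttest(tdncd_features(prof$tdncd),
                                            prof$manifest))
    rates[r] <- mean(meta$combined_p < 0.05)
    pooled[[r]] <- meta$combined_p
  }
  p_all <- unlist(pooled)
  ks_d <- as.numeric(suppressWarnings(
    stats::ks.test(p_all, "punif")$statistic))
  list(rates = rates, pooled_rate = mean(rates),
       mc_se = stats::sd(rates) / sqrt(n_replicates),
       ks_d = ks_d, n_features = length(pooled[[1]]),
       n_subjects = sum(gs))
}

#' Parameter-recovery experiment: ranking planted regions
#'
#' Generates state-switching cohorts with the standard planted effect
#' (5 affected regions among `R`), runs the meta-analysis, scores each
#' region by its strongest combined evidence across time distances, and
#' measures how well that score ranks planted above unaffected regions
#' (Mann-Whitney AUC), once per seed.
#'
#' @param n_seeds Number of independent cohorts (default 10).
#' @param subjects_per_group NC and AD subjects per site (default 25).
#' @param R Number of regions (default 40).
#' @param effect_delta Planted effect size for the AD group (default 1).
#' @param n_sites Number of sites (default 7).
#' @param seed Master seed.
#' @return A list with per-seed `aucs` and their `mean_auc`, the
#'   replicated-experiment `pooled_auc` (each region's evidence averaged
#'   over the seeds before ranking — the better-powered estimator of the
#'   same ranking property, since the planted set is identical in every
#'   replicate), and the last cohort's per-region flags (`flagged`,
#'   `affected`).
#' @export
planted_recovery <- function(n_seeds = 10, subjects_per_group = 25, R = 40,
                             effect_delta = 1, n_sites = 7, seed = 1) {
  gs <- matrix(c(subjects_per_group, 0, subjects_per_group),
               n_sites, 3, byrow = TRUE)
  aucs <- numeric(n_seeds)
  evidence <- matrix(0, R, n_seeds)
  truth <- flagged <- affected <- NULL
  for (r in seq_len(n_seeds)) {
    spec <- synthetic_spec(R = R, n_sites = n_sites, group_sizes = gs,
                           effect_delta = c(NC = 0,
                                            MCI = effect_delta / 2,
                                            AD = effect_delta),
                           seed = derive_seed(seed, 1000L, r))
    coh <- generate_cohort(spec)
    prof <- cohort_profiles(coh, kinds = "tdncd")
    meta <- stouffer_combine(sitewise_ttest(tdncd_features(prof$tdncd),
                                            prof$manifest))
    D <- ncol(prof$tdncd[[1]]$matrix)
    sig <- meta_significance(meta, tdncd_annotation(R, D),
                             family = "tdncd_24", family_size = D)
    score <- -log10(tapply(sig$features$combined_p, sig$features$roi, min))
    truth <- seq_len(R) %in% coh$ground_truth$affected_rois
    evidence[, r] <- as.numeric(score)
    aucs[r] <- rank_auc(evidence[, r], truth)
    flagged <- which(sig$rois$flagged)
    affected <- coh$ground_truth$affected_rois
  }
  list(aucs = aucs, mean_auc = mean(aucs),
       pooled_auc = rank_auc(rowMeans(evidence), truth),
       flagged = flagged, affected = affected)
}

#' Positive-control vs null-control classification experiment
#'
#' Runs the nested leave-one-site-out classifier on a planted-effect cohort
#' and on a matched zero-effect cohort, using tdNCD features. The planted
#' run should beat chance (pooled binomial test) and its own null control.
#'
#' @inheritParams planted_recovery
#' @param model Classifier family (default `"lr"`).
#' @return A list with `acc_planted`, `acc_null` (pooled percent accuracy),
#'   `binom_p` (one-sided binomial test of the planted run against chance),
#'   `n_test`, and both `loso_report` objects.
#' @export
loso_contrast <- function(subjects_per_group = 25, R = 40, effect_delta = 1,
                          n_sites = 7, model = "lr", seed = 1) {
  gs <- matrix(c(subjects_per_group, 0, subjects_per_group),
               n_sites, 3, byrow = TRUE)
  run <- function(delta, sub_seed) {
    spec <- synthetic_spec(R = R, n_sites = n_sites, group_sizes = gs,
                           effect_delta = c(NC = 0, MCI = delta / 2,
                                            AD = delta),
                           seed = sub_seed)
    prof <- cohort_profiles(generate_cohort(spec), kinds = "tdncd")
    X <- build_feature_table(prof, "tdncd_roi_distance")
    nested_loso(X, prof$manifest, classifier_spec(model, seed = sub_seed),
                task = "nc_vs_ad")
  }
  rep_planted <- run(effect_delta, derive_seed(seed, 2000L, 1L))
  rep_null <- run(0, derive_seed(seed, 2000L, 2L))
  pooled_acc <- function(rep) {
    ok <- rep$folds$status == "ok"
    n <- sum(rep$folds$n_test[ok])
    correct <- sum(round(rep$folds$ACC[ok] * rep$folds$n_test[ok] / 100))
    list(acc = 100 * correct / n, correct = correct, n = n)
  }
  a <- pooled_acc(rep_planted); b <- pooled_acc(rep_null)
  bt <- stats::binom.test(a$correct, a$n, p = 0.5,
                          alternative = "greater")
  list(acc_planted = a$acc, acc_null = b$acc, binom_p = bt$p.value,
       n_test = a$n, report_planted = rep_planted, report_null = rep_null)
}

#' Leakage canary: a held-out-site indicator must not help
#'
#' Builds a cohort whose labels are pure noise but whose feature table
#' contains the site-indicator columns. Any leak of test-site information
#' into feature selection or standardisation would let the indicator raise
#' accuracy; a hygienic pipeline stays at chance.
#'
#' @param n_sites Number of sites (default 7).
#' @param n_per_site Subjects per site (default 30, labels balanced).
#' @param n_noise Number of pure-noise features (default 193).
#' @param model Classifier family (default `"lr"`).
#' @param seed Master seed.
#' @return A list with pooled `acc` (percent), `binom_p` (two-sided test
#'   against chance), `n_test`, and the `loso_report`.
#' @export
leakage_canary <- function(n_sites = 7, n_per_site = 30, n_noise = 193,
                           model = "lr", seed = 1) {
  with_seed(derive_seed(seed, 3000L), {
    n <- n_sites * n_per_site
    man <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                      site_id = rep(sprintf("site%d", seq_len(n_sites)),
                                    each = n_per_site),
                      diagnosis = as.vector(replicate(n_sites,
                        sample(rep(c("NC", "AD"), length.out = n_per_site)))),
                      mmse = NA_real_)
    site_dummies <- outer(man$site_id, sprintf("site%d", seq_len(n_sites)),
                          `==`) * 1
    X <- cbind(site_dummies, matrix(stats::rnorm(n * n_noise), n, n_noise))
    rownames(X) <- man$subject_id
    colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
    attr(X, "kind") <- rep("tdncd_roi_distance", ncol(X))
    rep1 <- nested_loso(X, man, classifier_spec(model, seed = seed),
                        task = "nc_vs_ad")
    ok <- rep1$folds$status == "ok"
    n_test <- sum(rep1$folds$n_test[ok])
    correct <- sum(round(rep1$folds$ACC[ok] * rep1$folds$n_test[ok] / 100))
    bt <- stats::binom.test(correct, n_test, p = 0.5)
    list(acc = 100 * correct / n_test, binom_p = bt$p.value,
         n_test = n_test, report = rep1)
  })
}
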