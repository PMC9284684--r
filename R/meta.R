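# Vectorised two-sample t-test over the columns of two matrices.
# Pooled-variance (Student) by default; Welch optional.
col_ttest <- function(Xa, Xb, var_equal = TRUE) {
  na <- nrow(Xa); nb <- nrow(Xb)
  ma <- colMeans(Xa); mb <- colMeans(Xb)
  va <- colSums(sweep(Xa, 2L, ma, "-")^2) / (na - 1)
  vb <- colSums(sweep(Xb, 2L, mb, "-")^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  t[se == 0 & ma == mb] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = pmin(p, 1), df = df, n_a = na, n_b = nb)
}

#' Site-wise two-sample t-tests on a feature table
#'
#' Runs a two-sided two-sample t-test (Student pooled variance by default)
#' between two diagnosis groups independently at every acquisition site, for
#' every feature column. Sites with fewer than `min_per_group` subjects in
#' either group are skipped with a warning and excluded from any downstream
#' combination.
#'
#' @param features Numeric matrix, subjects in rows (rownames = subject ids)
#'   by features in columns (colnames = feature ids).
#' @param manifest Data frame with columns `subject_id`, `site_id`,
#'   `diagnosis` covering every row of `features`.
#' @param group_a,group_b Diagnosis labels to compare (default NC vs AD);
#'   the effect sign is positive when group A exceeds group B.
#' @param var_equal Use the pooled-variance Student test (`TRUE`, default)
#'   or Welch's test.
#' @param min_per_group Minimum subjects per group per site (default 2).
#' @return A data frame of class `site_test_result` with one row per
#'   (site, feature): `site_id`, `feature_id`, `t_stat`, `p_two_sided`,
#'   `effect_sign`, `n_group_a`, `n_group_b`, `n_total`.
#' @export
sitewise_ttest <- function(features, manifest, group_a = "NC", group_b = "AD",
                           var_equal = TRUE, min_per_group = 2L) {
  features <- as.matrix(features)
  if (is.null(rownames(features)) ||
      !all(rownames(features) %in% manifest$subject_id))
    stop("feature rows must be named by subject ids present in the manifest")
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%05d", seq_len(ncol(features)))
  meta <- manifest[match(rownames(features), manifest$subject_id), ]
  out <- list()
  for (s in unique(meta$site_id)) {
    ia <- which(meta$site_id == s & meta$diagnosis == group_a)
    ib <- which(meta$site_id == s & meta$diagnosis == group_b)
    if (length(ia) < min_per_group || length(ib) < min_per_group) {
      warning(sprintf("site %s skipped: %d %s / %d %s subjects (need >= %d each)",
                      s, length(ia), group_a, length(ib), group_b,
                      min_per_group))
      next
    }
    tt <- col_ttest(features[ia, , drop = FALSE],
                    features[ib, , drop = FALSE], var_equal = var_equal)
    out[[s]] <- data.frame(site_id = s, feature_id = colnames(features),
                           t_stat = tt$t, p_two_sided = tt$p,
                           effect_sign = ifelse(tt$t < 0, -1L, 1L),
                           n_group_a = tt$n_a, n_group_b = tt$n_b,
                           n_total = tt$n_a + tt$n_b,
                           row.names = NULL)
  }
  if (length(out) == 0L) stop("no site had enough subjects in both groups")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("site_test_result", "data.frame")
  res
}

#' Weighted Liptak-Stouffer combination across sites
#'
#' Combines per-site two-sided p-values into one meta-analytic z and p per
#' feature. Each site's p is converted to a signed z-score,
#' `z_i = sign(t_i) * qnorm(1 - p_i / 2)`, the z-scores are pooled with
#' weights equal to the square root of the site's sample size,
#' `z = sum(w_i z_i) / sqrt(sum(w_i^2))`, and the combined two-sided p is
#' `2 * (1 - pnorm(|z|))`. Sites with opposite effect directions cancel.
#'
#' @param results A `site_test_result` data frame from [sitewise_ttest()].
#' @return A data frame of class `meta_result` with one row per feature:
#'   `feature_id`, `combined_z`, `combined_p`, `n_sites_used`.
#' @export
stouffer_combine <- function(results) {
  stopifnot(all(c("feature_id", "p_two_sided", "effect_sign", "n_total")
                %in% names(results)))
  p <- results$p_two_sided
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to the smallest representable positive value")
    p <- pmax(p, .Machine$double.xmin)
  }
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  # upper-tail form keeps z finite down to the smallest representable p
  z_i <- results$effect_sign * stats::qnorm(p / 2, lower.tail = FALSE)
  w <- sqrt(results$n_total)
  f <- factor(results$feature_id, levels = unique(results$feature_id))
  num <- rowsum(w * z_i, f)
  den <- sqrt(rowsum(w^2, f))
  k <- as.integer(rowsum(rep(1L, length(w)), f))
  z <- as.numeric(num / den)
  out <- data.frame(feature_id = levels(f), combined_z = z,
                    combined_p = pmin(2 * stats::pnorm(-abs(z)), 1),
                    n_sites_used = k, row.names = NULL)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Per-test Bonferroni threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param family_size Number of tests in the family (24 time distances for
#'   tdNCD; 264 for the FC comparison).
#' @return `alpha / family_size`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, family_size) {
  stopifnot(alpha > 0, alpha < 1, family_size >= 1)
  alpha / family_size
}

#' Bonferroni significance flags and ROI-level summary
#'
#' Applies the Bonferroni-corrected threshold to combined p-values and
#' aggregates to the region level. For the tdNCD family the correction is
#' over the 24 time distances (`alpha / 24`) and a region is flagged when any
#' of its distances is significant. For the FC-edge family the correction
#' uses a family size equal to the number of regions (`alpha / 264` under the
#' default parcellation); the summary counts significant edges incident to
#' each region and flags regions with a nonzero count.
#'
#' @param meta A `meta_result` from [stouffer_combine()].
#' @param annotation Data frame mapping `feature_id` to regions: columns
#'   `feature_id` and `roi` (tdNCD; plus optional `distance_seconds`) or
#'   `roi_a`/`roi_b` (FC edges). See [tdncd_annotation()] and
#'   [edge_annotation()].
#' @param family `"tdncd_24"` or `"fc_264"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param family_size Override for the Bonferroni family size; defaults to
#'   24 (`tdncd_24`) or the number of distinct regions (`fc_264`).
#' @return A list of class `meta_significance`: `features` (the meta table
#'   with a `significant` flag), `rois` (per-region summary), `threshold`,
#'   `family`.
#' @export
meta_significance <- function(meta, annotation,
                              family = c("tdncd_24", "fc_264"),
                              alpha = 0.05, family_size = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(meta, "data.frame"),
            all(meta$feature_id %in% annotation$feature_id))
  ann <- annotation[match(meta$feature_id, annotation$feature_id), ]
  if (family == "tdncd_24") {
    if (!"roi" %in% names(ann)) stop("tdncd annotation needs a 'roi' column")
    N <- family_size %||% 24
  } else {
    if (!all(c("roi_a", "roi_b") %in% names(ann)))
      stop("fc annotation needs 'roi_a' and 'roi_b' columns")
    N <- family_size %||% length(unique(c(ann$roi_a, ann$roi_b)))
  }
  thr <- bonferroni_threshold(alpha, N)
  feats <- cbind(meta, ann[setdiff(names(ann), "feature_id")])
  feats$significant <- feats$combined_p < thr
  if (family == "tdncd_24") {
    rois <- data.frame(roi = unique(ann$roi))
    agg <- tapply(feats$significant, feats$roi, any)
    rois$flagged <- as.logical(agg[as.character(rois$roi)])
    rois$n_significant <- as.integer(
      tapply(feats$significant, feats$roi, sum)[as.character(rois$roi)])
  } else {
    all_rois <- sort(unique(c(ann$roi_a, ann$roi_b)))
    sig <- feats[feats$significant, ]
    cnt <- table(factor(c(sig$roi_a, sig$roi_b), levels = all_rois))
    rois <- data.frame(roi = all_rois,
                       n_significant = as.integer(cnt),
                       flagged = as.integer(cnt) > 0L)
  }
  structure(list(features = feats, rois = rois, threshold = thr,
                 family = family, alpha = alpha, family_size = N),
            class = "meta_significance")
}

#' @export
print.meta_significance <- function(x, ...) {
  cat(sprintf("meta-analysis (%s): %d features, threshold p < %.4g (alpha %g / %d)\n",
              x$family, nrow(x$features), x$threshold, x$alpha, x$family_size))
  cat(sprintf("  %d significant features; %d of %d regions flagged\n",
              sum(x$features$significant), sum(x$rois$flagged), nrow(x$rois)))
  invisible(x)
}

#' Feature annotation for tdNCD feature tables
#'
#' @param R Number of regions.
#' @param D Number of time distances.
#' @param step_seconds Window step in seconds (default 10).
#' @return Data frame with `feature_id`, `roi`, `distance_seconds` matching
#'   the column order of [tdncd_features()].
#' @export
tdncd_annotation <- function(R, D, step_seconds = 10) {
  roi <- rep(seq_len(R), each = D)
  d <- rep(seq_len(D), times = R)
  data.frame(feature_id = sprintf("tdNCD_r%03d_d%02d", roi, d),
             roi = roi, distance_seconds = d * step_seconds)
}

#' Feature annotation for FC-edge feature tables
#'
#' @param R Number of regions.
#' @return Data frame with `feature_id`, `roi_a`, `roi_b` matching the
#'   column order of [sfc_features()] (upper triangle, row-major).
#' @export
edge_annotation <- function(R) {
  idx <- which(upper.tri(diag(R)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(feature_id = sprintf("sFC_r%03d_r%03d", idx[, 1L], idx[, 2L]),
             roi_a = idx[, 1L], roi_b = idx[, 2L])
}

#' Write meta-analysis tables to TSV files
#'
#' @param x A `meta_significance` object.
#' @param feature_path,roi_path Output paths for the per-feature and
#'   per-region tables.
#' @return Invisibly, `x`.
#' @export
write_meta <- function(x, feature_path, roi_path) {
  stopifnot(inherits(x, "meta_significance"))
  write_table_atomic(x$features, feature_path)
  write_table_atomic(x$rois, roi_path)
  invisible(x)
}
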