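#' Classification metrics (percent)
#'
#' Two-class mode (a `positive_class`): accuracy, sensitivity (recall of the
#' positive class), specificity (recall of the rest), and F1 with the
#' positive class as positive. Macro mode (`positive_class = "macro"`):
#' unweighted means of the per-class one-vs-rest sensitivity, specificity
#' and F1; classes absent from the truth are dropped from the macro mean
#' with a warning. All values are percentages.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive_class The positive class label (default `"AD"`), or
#'   `"macro"` for macro-averaged multi-class metrics.
#' @return Named numeric vector `c(ACC, SEN, SPE, F1)` in percent.
#' @export
compute_metrics <- function(truth, predicted, positive_class = "AD") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) > 0L)
  acc <- 100 * mean(truth == predicted)
  one_vs_rest <- function(cls) {
    tp <- sum(truth == cls & predicted == cls)
    fn <- sum(truth == cls & predicted != cls)
    fp <- sum(truth != cls & predicted == cls)
    tn <- sum(truth != cls & predicted != cls)
    sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    c(SEN = sen, SPE = spe, F1 = f1)
  }
  if (identical(positive_class, "macro")) {
    classes <- sort(unique(c(truth, predicted)))
    absent <- setdiff(classes, unique(truth))
    if (length(absent) > 0L) {
      warning("class(es) absent from truth excluded from macro mean: ",
              paste(absent, collapse = ", "))
      classes <- setdiff(classes, absent)
    }
    per <- vapply(classes, one_vs_rest, numeric(3L))
    out <- c(ACC = acc, 100 * rowMeans(per, na.rm = TRUE))
  } else {
    if (!positive_class %in% truth)
      warning("positive class ", positive_class, " absent from truth")
    out <- c(ACC = acc, 100 * one_vs_rest(positive_class))
  }
  names(out) <- c("ACC", "SEN", "SPE", "F1")
  out
}

# Fit-and-score helper for one train/test split: feature selection and
# column standardisation are fitted strictly on the training rows.
fit_split <- function(features, manifest, train_ids, spec, hp, thresholds,
                      classes, seed) {
  tr <- features[train_ids, , drop = FALSE]
  attr(tr, "kind") <- attr(features, "kind")
  lab <- manifest$diagnosis[match(train_ids, manifest$subject_id)]
  mask <- select_features(tr, lab, thresholds = thresholds,
                          group_a = "NC", group_b = "AD")
  Xtr <- tr[, mask, drop = FALSE]
  scaler <- fit_scaler(Xtr)
  Xtr <- apply_scaler(scaler, Xtr)
  y <- factor(lab, levels = classes)
  model <- fit_classifier(spec, Xtr, y, hp = hp, seed = seed)
  list(model = model, mask = mask, scaler = scaler)
}

predict_split <- function(fitted, features, ids) {
  X <- features[ids, which(fitted$mask), drop = FALSE]
  X <- apply_scaler(fitted$scaler, X)
  predict_prob(fitted$model, X)
}

#' Nested leave-one-site-out evaluation
#'
#' Outer loop: each acquisition site in turn is the held-out test set. Inner
#' loop: for every hyperparameter setting, each remaining site in turn
#' serves as validation while the others train; the setting with the best
#' mean validation accuracy wins (ties resolve toward the smaller learning
#' rate, then fewer training passes). The winning setting is refit on all
#' non-test sites and scored on the held-out site. Feature selection and
#' feature standardisation are fitted inside the training rows of every
#' split, never on held-out data.
#'
#' For the two-class task the refit model is additionally applied to the
#' held-out site's MCI subjects so their decision scores enter the
#' cognition correlation analysis.
#'
#' @param features A [build_feature_table()] matrix covering all subjects.
#' @param manifest Data frame with `subject_id`, `site_id`, `diagnosis` and
#'   optionally `mmse`.
#' @param spec A [classifier_spec()].
#' @param task `"nc_vs_ad"` (two-class) or `"nc_mci_ad"` (three-class).
#' @param thresholds Per-kind selection thresholds
#'   (default [default_selection_thresholds()]).
#' @return An object of class `loso_report`: `folds` (per-site metrics,
#'   chosen hyperparameters, selected-feature counts), `scores`
#'   (per-subject AD-class decision scores with site, diagnosis, MMSE),
#'   `task`, `model`, `seed`.
#' @export
nested_loso <- function(features, manifest, spec,
                        task = c("nc_vs_ad", "nc_mci_ad"),
                        thresholds = default_selection_thresholds()) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "classifier_spec"))
  classes <- if (task == "nc_vs_ad") c("NC", "AD") else c("NC", "MCI", "AD")
  sites <- unique(manifest$site_id)
  if (length(sites) < 3L) stop("need at least 3 sites for nested evaluation")
  grid <- hp_grid(spec)
  in_task <- manifest$diagnosis %in% classes
  folds <- list(); scores <- list()
  for (fi in seq_along(sites)) {
    s <- sites[fi]
    test_ids <- manifest$subject_id[in_task & manifest$site_id == s]
    train_man <- manifest[in_task & manifest$site_id != s, ]
    missing_cls <- classes[!classes %in% manifest$diagnosis[
      in_task & manifest$site_id == s]]
    if (length(missing_cls) > 0L) {
      warning(sprintf("fold %s aborted: test site lacks class(es) %s",
                      s, paste(missing_cls, collapse = ", ")))
      folds[[s]] <- data.frame(site = s, status = "missing", ACC = NA_real_,
                               SEN = NA_real_, SPE = NA_real_, F1 = NA_real_,
                               n_test = length(test_ids),
                               n_selected = NA_integer_,
                               learning_rate = NA_real_, epochs = NA_integer_)
      next
    }
    fold_seed <- derive_seed(spec$seed, fi)
    # inner hyperparameter search (skipped for a single-setting grid)
    best_hp <- grid[1L, , drop = FALSE]
    if (nrow(grid) > 1L) {
      inner_sites <- unique(train_man$site_id)
      mean_acc <- numeric(nrow(grid))
      for (gi in seq_len(nrow(grid))) {
        accs <- numeric(0)
        for (v in inner_sites) {
          tr_ids <- train_man$subject_id[train_man$site_id != v]
          va_ids <- train_man$subject_id[train_man$site_id == v]
          ok <- all(classes %in% train_man$diagnosis[train_man$site_id != v])
          if (!ok) next
          f <- fit_split(features, manifest, tr_ids, spec,
                         grid[gi, , drop = FALSE], thresholds, classes,
                         seed = derive_seed(fold_seed, gi, match(v, sites)))
          P <- predict_split(f, features, va_ids)
          pred <- colnames(P)[max.col(P, ties.method = "first")]
          accs <- c(accs, mean(pred == manifest$diagnosis[
            match(va_ids, manifest$subject_id)]))
        }
        mean_acc[gi] <- mean(accs)
      }
      best_hp <- grid[which.max(mean_acc), , drop = FALSE]
    }
    # refit on all non-test sites, score the held-out site
    f <- fit_split(features, manifest, train_man$subject_id, spec, best_hp,
                   thresholds, classes, seed = fold_seed)
    P <- predict_split(f, features, test_ids)
    truth <- manifest$diagnosis[match(test_ids, manifest$subject_id)]
    pred <- colnames(P)[max.col(P, ties.method = "first")]
    m <- compute_metrics(truth, pred,
                         positive_class = if (task == "nc_vs_ad") "AD"
                                          else "macro")
    folds[[s]] <- data.frame(site = s, status = "ok", ACC = m["ACC"],
                             SEN = m["SEN"], SPE = m["SPE"], F1 = m["F1"],
                             n_test = length(test_ids),
                             n_selected = sum(f$mask),
                             learning_rate =
                               if (spec$model == "fcnet")
                                 best_hp$learning_rate else NA_real_,
                             epochs = if (spec$model == "fcnet")
                                 as.integer(best_hp$epochs) else NA_integer_,
                             row.names = NULL)
    score_ids <- test_ids
    if (task == "nc_vs_ad") {
      mci_ids <- manifest$subject_id[manifest$site_id == s &
                                     manifest$diagnosis == "MCI"]
      if (length(mci_ids) > 0L) {
        Pm <- predict_split(f, features, mci_ids)
        P <- rbind(P, Pm)
        score_ids <- c(score_ids, mci_ids)
      }
    }
    sm <- manifest[match(score_ids, manifest$subject_id), ]
    scores[[s]] <- data.frame(subject_id = score_ids, site = s,
                              diagnosis = sm$diagnosis,
                              mmse = if ("mmse" %in% names(sm)) sm$mmse
                                     else NA_real_,
                              score = P[, "AD"], row.names = NULL)
  }
  structure(list(folds = do.call(rbind, c(folds, list(make.row.names = FALSE))),
                 scores = do.call(rbind, c(scores, list(make.row.names = FALSE))),
                 task = task, model = spec$model, seed = spec$seed),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  ok <- x$folds$status == "ok"
  cat(sprintf("leave-one-site-out report: %s, task %s, %d/%d folds evaluated\n",
              x$model, x$task, sum(ok), nrow(x$folds)))
  if (any(ok)) {
    m <- colMeans(x$folds[ok, c("ACC", "SEN", "SPE", "F1")])
    cat(sprintf("  mean ACC %.1f%%  SEN %.1f%%  SPE %.1f%%  F1 %.1f%%\n",
                m[1L], m[2L], m[3L], m[4L]))
  }
  invisible(x)
}

#' @export
summary.loso_report <- function(object, ...) {
  print(object)
  print(object$folds, row.names = FALSE)
  invisible(object)
}

#' Correlation between decision scores and cognitive ability
#'
#' Pearson correlation (with two-sided p) between the AD-class decision
#' score and the MMSE score over the pooled AD and MCI test subjects of a
#' leave-one-site-out report. A negative correlation indicates that higher
#' model-assessed disease probability accompanies lower cognitive scores.
#'
#' @param report A `loso_report` (or its `scores` data frame).
#' @return A list with `R`, `p`, `n`; `R` is `NA` with a warning when the
#'   scores are constant.
#' @export
decision_mmse_correlation <- function(report) {
  sc <- if (inherits(report, "loso_report")) report$scores else report
  sc <- sc[sc$diagnosis %in% c("AD", "MCI") & !is.na(sc$mmse), ]
  if (nrow(sc) < 3L)
    stop("need at least 3 AD/MCI subjects with MMSE scores")
  if (stats::sd(sc$score) == 0) {
    warning("constant decision scores: correlation undefined")
    return(list(R = NA_real_, p = NA_real_, n = nrow(sc)))
  }
  ct <- stats::cor.test(sc$score, sc$mmse, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = nrow(sc))
}

#' Paired comparison of two leave-one-site-out reports
#'
#' Paired two-sided t-test across per-fold metric values, one test per
#' metric. Both reports must share the identical fold (site) structure.
#' A constant nonzero difference makes the paired t degenerate; it is
#' reported with `p = 0` and flagged.
#'
#' @param report_a,report_b `loso_report` objects with identical folds.
#' @param metrics Which per-fold metrics to compare.
#' @return Data frame with `metric`, `mean_diff` (a minus b), `t`, `p`,
#'   `degenerate`.
#' @export
compare_models_paired_t <- function(report_a, report_b,
                                    metrics = c("ACC", "SEN", "SPE", "F1")) {
  stopifnot(inherits(report_a, "loso_report"),
            inherits(report_b, "loso_report"))
  if (!identical(report_a$folds$site, report_b$folds$site))
    stop("reports have mismatched fold structures")
  ok <- report_a$folds$status == "ok" & report_b$folds$status == "ok"
  out <- lapply(metrics, function(m) {
    d <- report_a$folds[ok, m] - report_b$folds[ok, m]
    if (all(d == 0))
      return(data.frame(metric = m, mean_diff = 0, t = 0, p = 1,
                        degenerate = FALSE))
    if (stats::sd(d) == 0)
      return(data.frame(metric = m, mean_diff = mean(d),
                        t = sign(mean(d)) * Inf, p = 0, degenerate = TRUE))
    tt <- stats::t.test(d)
    data.frame(metric = m, mean_diff = mean(d),
               t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  })
  do.call(rbind, out)
}
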