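#' Classifier specification
#'
#' Describes one of the five model families and its hyperparameter grid.
#' Only the network has a real grid (training passes and Adam learning
#' rate); the classical baselines use fixed, overridable settings.
#'
#' @param model One of `"fcnet"`, `"svm"` (linear kernel), `"knn"`,
#'   `"lr"` (L2-regularised logistic regression), `"lda"`.
#' @param seed Integer seed recorded in every report and used to derive all
#'   fit-time randomness.
#' @param grid For `fcnet`, a list with `learning_rate` and `epochs`
#'   candidate vectors; ignored otherwise.
#' @param cost SVM cost parameter (default 1).
#' @param k Neighbour count for KNN (default 5).
#' @param lambda Ridge penalty for logistic regression (default 0.01).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(model = c("fcnet", "svm", "knn", "lr", "lda"),
                            seed = 1L,
                            grid = list(learning_rate = c(1e-2, 1e-3, 1e-4),
                                        epochs = c(50L, 100L, 200L)),
                            cost = 1, k = 5L, lambda = 0.01) {
  model <- match.arg(model)
  if (model == "fcnet" &&
      (length(grid$learning_rate) == 0L || length(grid$epochs) == 0L))
    stop("fcnet needs a non-empty hyperparameter grid")
  structure(list(model = model, seed = as.integer(seed), grid = grid,
                 cost = cost, k = as.integer(k), lambda = lambda),
            class = "classifier_spec")
}

# Hyperparameter candidates as a data frame, ordered so that ties in the
# inner loop resolve toward the smaller learning rate, then fewer passes.
hp_grid <- function(spec) {
  if (spec$model != "fcnet")
    return(data.frame(dummy = 1))
  g <- expand.grid(learning_rate = sort(spec$grid$learning_rate),
                   epochs = sort(spec$grid$epochs))
  g[order(g$learning_rate, g$epochs), , drop = FALSE]
}

fit_classifier <- function(spec, X, y, hp = NULL, seed = spec$seed) {
  y <- droplevels(as.factor(y))
  pad <- spec$model == "lr" && ncol(X) < 2L
  if (pad) X <- cbind(X, .pad = 0)  # glmnet requires >= 2 columns
  fit <- switch(spec$model,
    fcnet = fcnet_fit(X, y, epochs = hp$epochs,
                      learning_rate = hp$learning_rate, seed = seed),
    svm = e1071::svm(X, y, kernel = "linear", cost = spec$cost,
                     scale = FALSE),
    knn = caret::knn3(X, y, k = spec$k),
    lr = glmnet::glmnet(X, y,
                        family = if (nlevels(y) > 2L) "multinomial"
                                 else "binomial",
                        alpha = 0, lambda = spec$lambda),
    lda = MASS::lda(X, grouping = y))
  structure(list(spec = spec, fit = fit, levels = levels(y), pad = pad),
            class = "tdncd_classifier")
}

# Class-probability predictions for every model family, as an
# n x n_classes matrix with columns named by class. Margin-based models
# (SVM) are mapped through a logistic link of the decision margin.
predict_prob <- function(object, X) {
  spec <- object$spec; lev <- object$levels; fit <- object$fit
  if (isTRUE(object$pad)) X <- cbind(X, .pad = 0)
  n <- nrow(X)
  P <- switch(spec$model,
    fcnet = predict(fit, X),
    svm = {
      dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
      S <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
      for (cn in colnames(dv)) {       # one-vs-one margins, e.g. "AD/NC"
        pair <- strsplit(cn, "/", fixed = TRUE)[[1L]]
        pr <- stats::plogis(dv[, cn])
        S[, pair[1L]] <- S[, pair[1L]] + pr
        S[, pair[2L]] <- S[, pair[2L]] + (1 - pr)
      }
      S / rowSums(S)
    },
    knn = predict(fit, X, type = "prob"),
    lr = {
      pr <- predict(fit, X, type = "response", s = spec$lambda)
      if (length(dim(pr)) == 3L) pr[, , 1L]
      else cbind(1 - pr[, 1L], pr[, 1L],
                 deparse.level = 0)      # binomial: P(second level)
    },
    lda = predict(fit, X)$posterior)
  P <- as.matrix(P)
  if (is.null(colnames(P)) || !all(lev %in% colnames(P)))
    colnames(P) <- lev
  P[, lev, drop = FALSE]
}

predict_class <- function(object, X) {
  P <- predict_prob(object, X)
  factor(colnames(P)[max.col(P, ties.method = "first")],
         levels = object$levels)
}
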