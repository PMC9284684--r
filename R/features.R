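upper_tri_index <- function(R) {
  idx <- which(upper.tri(diag(R)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Flatten per-subject tdNCD profiles into a feature matrix
#'
#' @param tdncd_list Named list (subject id -> `tdncd` object), all sharing
#'   the same `R x D` dimension.
#' @return Numeric matrix, subjects x (R*D), columns ordered by region then
#'   distance and named `tdNCD_r###_d##`.
#' @export
tdncd_features <- function(tdncd_list) {
  mats <- lapply(tdncd_list, function(x) {
    if (inherits(x, "tdncd")) x$matrix else as.matrix(x)
  })
  d0 <- dim(mats[[1L]])
  for (nm in names(mats))
    if (!all(dim(mats[[nm]]) == d0))
      stop("subject ", nm, " has mismatched tdNCD dimensions")
  out <- t(vapply(mats, function(m) as.numeric(t(m)),
                  numeric(d0[1L] * d0[2L])))
  rownames(out) <- names(tdncd_list)
  colnames(out) <- tdncd_annotation(d0[1L], d0[2L])$feature_id
  out
}

#' Flatten per-subject static FC matrices into an edge feature matrix
#'
#' @param sfc_list Named list (subject id -> symmetric `R x R` matrix).
#' @return Numeric matrix, subjects x R(R-1)/2, upper-triangle edges in
#'   row-major order, named `sFC_r###_r###`.
#' @export
sfc_features <- function(sfc_list) {
  R <- nrow(sfc_list[[1L]])
  for (nm in names(sfc_list))
    if (!all(dim(sfc_list[[nm]]) == c(R, R)))
      stop("subject ", nm, " has mismatched FC dimensions")
  idx <- upper_tri_index(R)
  lin <- (idx[, 2L] - 1L) * R + idx[, 1L]
  out <- t(vapply(sfc_list, function(m) as.numeric(m)[lin],
                  numeric(nrow(idx))))
  rownames(out) <- names(sfc_list)
  colnames(out) <- edge_annotation(R)$feature_id
  out
}

#' Flatten per-subject dFC stacks into a window-edge feature matrix
#'
#' @param dfc_list Named list (subject id -> `dfc_stack`), all sharing the
#'   same window count and ROI count.
#' @return Numeric matrix, subjects x (n_windows * R(R-1)/2), columns ordered
#'   by window then edge and named `dFC_w##_r###_r###`.
#' @export
dfc_features <- function(dfc_list) {
  d0 <- dim(dfc_list[[1L]]$tensor)
  for (nm in names(dfc_list))
    if (!all(dim(dfc_list[[nm]]$tensor) == d0))
      stop("subject ", nm, " has mismatched dFC dimensions")
  nw <- d0[1L]; R <- d0[2L]
  idx <- upper_tri_index(R)
  cols <- sprintf("dFC_w%02d_r%03d_r%03d",
                  rep(seq_len(nw), each = nrow(idx)),
                  rep(idx[, 1L], nw), rep(idx[, 2L], nw))
  out <- t(vapply(dfc_list, function(s) {
    as.numeric(vapply(seq_len(nw), function(w) s$tensor[w, , ][idx],
                      numeric(nrow(idx))))
  }, numeric(nw * nrow(idx))))
  rownames(out) <- names(dfc_list)
  colnames(out) <- cols
  out
}

#' Assemble a subject-by-feature table from per-subject matrices
#'
#' Binds the requested feature blocks in a deterministic order
#' (lexicographic by kind: `dfc_window_edge`, `sfc_edge`,
#' `tdncd_roi_distance`; within a kind by window/region/distance index).
#' Values are copied unchanged. The per-column feature kind is recorded in
#' the `"kind"` attribute and drives per-kind selection thresholds in
#' [select_features()].
#'
#' @param cohort A list with elements `manifest` (data frame with
#'   `subject_id`) and, per requested kind, `sfc` / `tdncd` / `dfc`: named
#'   lists keyed by subject id.
#' @param kinds Character subset of
#'   `c("dfc_window_edge", "sfc_edge", "tdncd_roi_distance")`.
#' @return A numeric matrix of class `feature_table` with attribute `kind`.
#' @export
build_feature_table <- function(cohort,
                                kinds = c("sfc_edge", "tdncd_roi_distance")) {
  valid <- c("dfc_window_edge", "sfc_edge", "tdncd_roi_distance")
  if (length(kinds) == 0L) stop("at least one feature kind must be requested")
  if (!all(kinds %in% valid))
    stop("unknown feature kind(s): ", paste(setdiff(kinds, valid), collapse = ", "))
  kinds <- sort(unique(kinds))
  ids <- cohort$manifest$subject_id
  blocks <- list(); kind_vec <- character(0)
  for (k in kinds) {
    src <- switch(k, dfc_window_edge = cohort$dfc, sfc_edge = cohort$sfc,
                  tdncd_roi_distance = cohort$tdncd)
    if (is.null(src)) stop("cohort lacks the matrices for kind ", k)
    missing <- setdiff(ids, names(src))
    if (length(missing) > 0L)
      stop("no ", k, " matrices for subject(s): ",
           paste(utils::head(missing, 3L), collapse = ", "))
    src <- src[ids]
    blk <- switch(k, dfc_window_edge = dfc_features(src),
                  sfc_edge = sfc_features(src),
                  tdncd_roi_distance = tdncd_features(src))
    blocks[[k]] <- blk
    kind_vec <- c(kind_vec, rep(k, ncol(blk)))
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- ids
  attr(out, "kind") <- kind_vec
  class(out) <- c("feature_table", class(out))
  out
}

#' Default per-kind feature-selection p-value thresholds
#'
#' Chosen so the number of surviving features stays on the order of the
#' number of subjects: 0.001 for static FC edges, 1e-5 for windowed dFC
#' edges, 0.05 for tdNCD features.
#'
#' @return Named numeric vector.
#' @export
default_selection_thresholds <- function() {
  c(sfc_edge = 0.001, dfc_window_edge = 1e-5, tdncd_roi_distance = 0.05)
}

#' Univariate t-test feature selection
#'
#' Keeps a column when the two-sided two-sample t-test between the two
#' training diagnosis groups falls below the threshold for its feature kind.
#' For a three-class task the contrast is NC vs AD. Must be applied to
#' training subjects only; [nested_loso()] enforces this.
#'
#' @param features A `feature_table` (or plain matrix, in which case a
#'   single threshold applies to all columns).
#' @param labels Diagnosis vector aligned to rows of `features`.
#' @param thresholds Named per-kind p-value cutoffs
#'   (default [default_selection_thresholds()]).
#' @param group_a,group_b The two diagnosis groups tested (default NC, AD).
#' @return Logical column mask with the per-column p-values in attribute
#'   `"p"`. Errors if no column survives.
#' @export
select_features <- function(features, labels,
                            thresholds = default_selection_thresholds(),
                            group_a = "NC", group_b = "AD") {
  labels <- as.character(labels)
  ia <- labels == group_a; ib <- labels == group_b
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop("need at least 2 subjects in each of ", group_a, " and ", group_b)
  tt <- col_ttest(features[ia, , drop = FALSE], features[ib, , drop = FALSE])
  kind <- attr(features, "kind")
  if (is.null(kind)) kind <- rep(names(thresholds)[1L], ncol(features))
  cut <- thresholds[kind]
  if (anyNA(cut)) stop("no threshold supplied for kind(s): ",
                       paste(unique(kind[is.na(cut)]), collapse = ", "))
  mask <- tt$p < cut
  mask[is.na(mask)] <- FALSE
  if (!any(mask))
    stop("feature selection kept zero columns; relax the threshold(s)")
  attr(mask, "p") <- tt$p
  mask
}

# Column-wise z-scoring fitted on training data; constant columns get unit
# scale so they map to zero rather than NaN.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colSums(sweep(X, 2L, mu, "-")^2) / max(nrow(X) - 1L, 1L))
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}
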