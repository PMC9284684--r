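# Per-window connectivity profile matrix: column n holds window slice row n
# with the self-connection (n, n) removed. Slices are symmetric, so the
# column-major off-diagonal extraction S[-n, n] equals row n without its
# diagonal entry.
profile_matrix <- function(slice) {
  R <- nrow(slice)
  matrix(slice[row(slice) != col(slice)], nrow = R - 1L)
}

#' Nodal connectivity diversity between two windows
#'
#' For one region, measures how different its connectivity profile is in two
#' windows of a dynamic FC stack: `1 - |cor(row_i, row_j)|`, where each row
#' is the region's correlations to all other regions (the self-connection is
#' removed before correlating). A value of 0 means the profile shape is
#' preserved (up to sign); 1 means complete reconfiguration. The same
#' row-distance applied to two static FC matrices is the state-level
#' connectivity diversity; use [ncd()] for that case.
#'
#' @param stack A [compute_dfc()] result.
#' @param window_i,window_j Window indices (1-based).
#' @param roi_n ROI index (1-based).
#' @return A number in `[0, 1]`.
#' @export
dncd_profile_distance <- function(stack, window_i, window_j, roi_n) {
  stopifnot(inherits(stack, "dfc_stack"))
  nw <- stack$n_windows; R <- dim(stack$tensor)[2L]
  if (window_i < 1L || window_i > nw || window_j < 1L || window_j > nw)
    stop("window index out of range")
  if (roi_n < 1L || roi_n > R) stop("ROI index out of range")
  a <- stack$tensor[window_i, roi_n, -roi_n]
  b <- stack$tensor[window_j, roi_n, -roi_n]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop(sprintf("constant connectivity profile for ROI %d in window %d",
                 roi_n, if (stats::sd(a) == 0) window_i else window_j))
  1 - abs(stats::cor(a, b))
}

#' State-level nodal connectivity diversity
#'
#' Row distance `1 - |cor|` between a region's connectivity profiles in two
#' static FC matrices (e.g. two conditions or mental states), with the
#' self-connection removed.
#'
#' @param fc_i,fc_j Symmetric FC matrices of identical dimension.
#' @param roi_n ROI index.
#' @return A number in `[0, 1]`.
#' @export
ncd <- function(fc_i, fc_j, roi_n) {
  stopifnot(is.matrix(fc_i), is.matrix(fc_j), all(dim(fc_i) == dim(fc_j)))
  a <- fc_i[roi_n, -roi_n]; b <- fc_j[roi_n, -roi_n]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop(sprintf("constant connectivity profile for ROI %d", roi_n))
  1 - abs(stats::cor(a, b))
}

#' Time-distance nodal connectivity diversity profile
#'
#' Averages the window-pair connectivity diversity over all pairs separated
#' by each time distance: entry `(n, d)` is the mean of
#' `dncd(i, i + d, n)` over `i = 1 .. T - d`, where `T` is the number of
#' windows. Column `d` therefore averages exactly `T - d` pairs, and the
#' last column is the single pair `(1, T)`. With 25 windows this gives 24
#' time distances per region.
#'
#' @param stack A [compute_dfc()] result with at least 2 windows.
#' @return An object of class `tdncd`: list with `matrix` (`R x (T-1)`,
#'   rows named by ROI), `distances_seconds`, `step_seconds`.
#' @export
compute_tdncd <- function(stack) {
  stopifnot(inherits(stack, "dfc_stack"))
  T_ <- stack$n_windows
  if (T_ < 2L) stop("need at least 2 windows to measure reconfiguration")
  R <- dim(stack$tensor)[2L]
  # pre-centre and scale each window's profile matrix once
  centred <- vector("list", T_)
  for (w in seq_len(T_)) {
    M <- profile_matrix(stack$tensor[w, , ])
    Mc <- sweep(M, 2L, colMeans(M), "-")
    ss <- sqrt(colSums(Mc^2))
    if (any(ss == 0))
      stop(sprintf("constant connectivity profile for ROI %d in window %d",
                   which(ss == 0)[1L], w))
    centred[[w]] <- list(Mc = Mc, ss = ss)
  }
  acc <- matrix(0, R, T_ - 1L)
  for (i in seq_len(T_ - 1L)) {
    ci <- centred[[i]]
    for (j in (i + 1L):T_) {
      cj <- centred[[j]]
      r <- colSums(ci$Mc * cj$Mc) / (ci$ss * cj$ss)
      acc[, j - i] <- acc[, j - i] + (1 - abs(r))
    }
  }
  mat <- sweep(acc, 2L, T_ - seq_len(T_ - 1L), "/")
  # numerical guard: |cor| can exceed 1 by rounding
  mat[mat < 0] <- 0
  rownames(mat) <- stack$roi_labels
  dists <- seq_len(T_ - 1L) * stack$step_seconds
  colnames(mat) <- as.character(dists)
  structure(list(matrix = mat, distances_seconds = dists,
                 step_seconds = stack$step_seconds,
                 subject_id = stack$subject_id, site_id = stack$site_id,
                 diagnosis = stack$diagnosis, mmse = stack$mmse),
            class = "tdncd")
}

#' @export
print.tdncd <- function(x, ...) {
  cat(sprintf("tdNCD profile: %d ROIs x %d time distances (%g .. %g s)\n",
              nrow(x$matrix), ncol(x$matrix), min(x$distances_seconds),
              max(x$distances_seconds)))
  cat(sprintf("  grand mean %.3f (0 = stable, 1 = full reconfiguration)\n",
              mean(x$matrix)))
  invisible(x)
}

#' @export
as.matrix.tdncd <- function(x, ...) x$matrix

#' Plot tdNCD-vs-time-distance curves
#'
#' Draws one reconfiguration curve per region over time distance, with the
#' regional mean overlaid.
#'
#' @param x A `tdncd` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.tdncd <- function(x, ...) {
  graphics::matplot(x$distances_seconds, t(x$matrix), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.3),
                    xlab = "time distance (s)", ylab = "tdNCD", ...)
  graphics::lines(x$distances_seconds, colMeans(x$matrix), lwd = 2,
                  col = "firebrick")
  invisible(x)
}

#' Write a tdNCD profile to a TSV file
#'
#' One row per ROI, one column per time distance (header gives the distance
#' in seconds).
#'
#' @param x A `tdncd` object.
#' @param path Output path; written atomically.
#' @return Invisibly, `path`.
#' @export
write_tdncd <- function(x, path) {
  stopifnot(inherits(x, "tdncd"))
  write_table_atomic(x$matrix, path, row.names = TRUE, col.names = NA)
}

#' Read a tdNCD profile written by [write_tdncd()]
#'
#' @param path Path to the TSV file.
#' @param step_seconds Window step used when the profile was computed;
#'   recovered from the column header by default.
#' @return A `tdncd` object (without subject metadata).
#' @export
read_tdncd <- function(path, step_seconds = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, comment.char = "#")
  mat <- as.matrix(df)
  dists <- as.numeric(colnames(mat))
  if (anyNA(dists)) stop("column header must give time distances in seconds")
  structure(list(matrix = mat, distances_seconds = dists,
                 step_seconds = step_seconds %||% (dists[1L]),
                 subject_id = NA_character_, site_id = NA_character_,
                 diagnosis = NA_character_, mmse = NA_real_),
            class = "tdncd")
}
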