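#' Static functional connectivity
#'
#' Pearson correlation between every pair of ROI columns over the full scan.
#'
#' @param ts An [roi_timeseries()] object with at least 3 frames.
#' @return A symmetric `R x R` correlation matrix with unit diagonal.
#' @export
compute_sfc <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  if (nrow(x) < 3L) stop("need at least 3 frames for a correlation")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI column(s): ",
         paste(which(sds == 0), collapse = ", "))
  m <- stats::cor(x)
  diag(m) <- 1
  m
}

#' Sliding-window dynamic functional connectivity
#'
#' Recomputes the pairwise Pearson correlation matrix inside successive
#' rectangular windows. Window `w` covers frames
#' `start_w .. start_w + window_frames - 1`; starts advance by `step_frames`
#' from the first frame, and trailing frames that do not fill a complete
#' window are dropped.
#'
#' @param ts An [roi_timeseries()] object.
#' @param cfg A [window_config()]; defaults to the standard 100 s window with
#'   10 s step.
#' @return An object of class `dfc_stack`: a list with `tensor`
#'   (`n_windows x R x R` array), `window_starts` (1-based first frame of
#'   each window), window geometry, and the subject metadata of `ts`.
#' @export
compute_dfc <- function(ts, cfg = window_config(tr_seconds = ts$tr_seconds)) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(cfg, "window_config"))
  x <- ts$values
  tf <- nrow(x); R <- ncol(x)
  nw <- count_windows(tf, cfg)
  starts <- 1L + (seq_len(nw) - 1L) * cfg$step_frames
  tensor <- array(NA_real_, dim = c(nw, R, R))
  for (w in seq_len(nw)) {
    seg <- x[starts[w]:(starts[w] + cfg$window_frames - 1L), , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0))
      stop(sprintf("ROI %d is constant within window %d",
                   which(sds == 0)[1L], w))
    cm <- stats::cor(seg)
    diag(cm) <- 1
    tensor[w, , ] <- cm
  }
  structure(list(tensor = tensor, window_starts = starts,
                 n_windows = nw, window_frames = cfg$window_frames,
                 step_frames = cfg$step_frames,
                 step_seconds = cfg$step_seconds,
                 tr_seconds = ts$tr_seconds,
                 roi_labels = ts$roi_labels,
                 subject_id = ts$subject_id, site_id = ts$site_id,
                 diagnosis = ts$diagnosis, mmse = ts$mmse),
            class = "dfc_stack")
}

#' @export
print.dfc_stack <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("dFC stack: %d windows x %d x %d ROIs (window %d frames, step %d)\n",
              d[1L], d[2L], d[3L], x$window_frames, x$step_frames))
  invisible(x)
}

#' @export
dim.dfc_stack <- function(x) dim(x$tensor)

#' Export a dFC stack as one TSV per window
#'
#' Writes `window_<ii>.tsv` files (zero-padded window index) plus a
#' `metadata.txt` sidecar recording window geometry and start frames.
#'
#' @param stack A `dfc_stack`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the directory.
#' @export
write_dfc <- function(stack, dir) {
  stopifnot(inherits(stack, "dfc_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (w in seq_len(stack$n_windows)) {
    m <- stack$tensor[w, , ]
    dimnames(m) <- list(stack$roi_labels, stack$roi_labels)
    write_table_atomic(m, file.path(dir, sprintf("window_%02d.tsv", w)),
                       row.names = TRUE, col.names = NA)
  }
  meta <- c(sprintf("window_frames\t%d", stack$window_frames),
            sprintf("step_frames\t%d", stack$step_frames),
            sprintf("tr_seconds\t%g", stack$tr_seconds),
            sprintf("window_starts\t%s",
                    paste(stack$window_starts, collapse = ",")))
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}
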