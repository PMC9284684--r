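#' Construct a validated ROI time-series object
#'
#' Holds one subject's preprocessed regional fMRI signals (rows = frames,
#' columns = regions of interest) together with acquisition and clinical
#' metadata. All downstream computations (static FC, sliding-window dynamic
#' FC, tdNCD) start from this object.
#'
#' @param values Numeric matrix, `T_frames` rows (time) by `R` columns (ROIs).
#'   All entries must be finite; at least 2 frames and 2 ROIs.
#' @param subject_id,site_id Identifiers carried through to reports.
#' @param diagnosis One of `"NC"`, `"MCI"`, `"AD"`.
#' @param mmse Mini-Mental State Exam score in `[0, 30]`, or `NA`.
#' @param tr_seconds Repetition time: seconds per frame (default 2).
#' @param roi_labels Optional character vector of length `R` (e.g. network
#'   names); defaults to the column names of `values`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id = "subject", site_id = "site1",
                           diagnosis = c("NC", "MCI", "AD"), mmse = NA_real_,
                           tr_seconds = 2, roi_labels = colnames(values)) {
  diagnosis <- match.arg(diagnosis)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("time series must have at least 2 frames and 2 ROIs")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at frame %d, ROI %d", bad[1L], bad[2L]))
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be a positive number")
  if (!is.na(mmse) && (mmse < 0 || mmse > 30))
    stop("mmse must lie in [0, 30] or be NA")
  if (!is.null(roi_labels) && length(roi_labels) != ncol(values))
    stop("roi_labels must have one entry per ROI column")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(ncol(values)))
  colnames(values) <- roi_labels
  structure(list(subject_id = subject_id, site_id = site_id,
                 diagnosis = diagnosis, mmse = mmse,
                 tr_seconds = tr_seconds, values = values,
                 roi_labels = roi_labels),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s (site %s, %s)\n",
              x$subject_id, x$site_id, x$diagnosis))
  cat(sprintf("  %d frames x %d ROIs, TR = %g s, MMSE = %s\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              ifelse(is.na(x$mmse), "NA", format(x$mmse))))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

#' Read an ROI time-series file
#'
#' Parses a tab-separated text file with one header row of ROI labels and one
#' row per frame. Every cell must be a finite number; parse failures report
#' the offending line or cell.
#'
#' @param path Path to the TSV file.
#' @param transposed If `TRUE` the file stores ROIs as rows and frames as
#'   columns and is transposed on read.
#' @inheritParams roi_timeseries
#' @return An `roi_timeseries` object.
#' @export
read_timeseries <- function(path, subject_id = basename(path),
                            site_id = "site1", diagnosis = "NC",
                            mmse = NA_real_, tr_seconds = 2,
                            transposed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(nf) < 2L) stop("empty or header-only file: ", path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow = nrow(df)))
  if (anyNA(m) || !all(is.finite(m))) {
    bad <- which(is.na(m) | !is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or non-finite cell in %s at data row %d, column %d (%s)",
                 path, bad[1L], bad[2L], names(df)[bad[2L]]))
  }
  colnames(m) <- names(df)
  if (transposed) {
    labs <- rownames(m) %||% sprintf("ROI%03d", seq_len(nrow(m)))
    m <- t(m); colnames(m) <- labs
  }
  roi_timeseries(m, subject_id = subject_id, site_id = site_id,
                 diagnosis = diagnosis, mmse = mmse, tr_seconds = tr_seconds)
}

#' Write an ROI time-series object to a TSV file
#'
#' @param ts An `roi_timeseries` object.
#' @param path Output path; written atomically.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  write_table_atomic(ts$values, path)
}
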