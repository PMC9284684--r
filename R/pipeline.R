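#' Compute per-subject connectivity profiles for a whole cohort
#'
#' Convenience wrapper running [compute_sfc()], [compute_dfc()] and
#' [compute_tdncd()] for every subject of an in-memory cohort or a manifest
#' pointing at time-series files.
#'
#' @param cohort A `synthetic_cohort` with in-memory series, or a manifest
#'   data frame whose `path` column points at TSV files.
#' @param cfg A [window_config()]; the TR is taken from each series.
#' @param kinds Which profile kinds to compute: subset of
#'   `c("sfc", "tdncd", "dfc")`.
#' @return A list with `manifest` and named lists `sfc`, `tdncd`, `dfc`
#'   (only the requested kinds), keyed by subject id — the shape expected
#'   by [build_feature_table()].
#' @export
cohort_profiles <- function(cohort, cfg = NULL, kinds = c("sfc", "tdncd")) {
  kinds <- match.arg(kinds, c("sfc", "tdncd", "dfc"), several.ok = TRUE)
  if (inherits(cohort, "synthetic_cohort")) {
    manifest <- cohort$manifest
    get_ts <- function(i) {
      if (!is.null(cohort$timeseries))
        cohort$timeseries[[manifest$subject_id[i]]]
      else read_timeseries(manifest$path[i],
                           subject_id = manifest$subject_id[i],
                           site_id = manifest$site_id[i],
                           diagnosis = manifest$diagnosis[i],
                           mmse = manifest$mmse[i],
                           tr_seconds = cohort$spec$tr_seconds)
    }
  } else {
    manifest <- as.data.frame(cohort)
    get_ts <- function(i) read_timeseries(manifest$path[i],
                                          subject_id = manifest$subject_id[i],
                                          site_id = manifest$site_id[i],
                                          diagnosis = manifest$diagnosis[i],
                                          mmse = manifest$mmse[i])
  }
  out <- list(manifest = manifest)
  need_dfc <- any(c("tdncd", "dfc") %in% kinds)
  sfc <- list(); tdn <- list(); dfc <- list()
  for (i in seq_len(nrow(manifest))) {
    ts <- get_ts(i)
    id <- manifest$subject_id[i]
    if ("sfc" %in% kinds) sfc[[id]] <- compute_sfc(ts)
    if (need_dfc) {
      use_cfg <- cfg %||% window_config(tr_seconds = ts$tr_seconds)
      stack <- compute_dfc(ts, use_cfg)
      if ("dfc" %in% kinds) dfc[[id]] <- stack
      if ("tdncd" %in% kinds) tdn[[id]] <- compute_tdncd(stack)
    }
  }
  if ("sfc" %in% kinds) out$sfc <- sfc
  if ("tdncd" %in% kinds) out$tdncd <- tdn
  if ("dfc" %in% kinds) out$dfc <- dfc
  out
}
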