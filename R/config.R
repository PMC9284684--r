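#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with defaults matching the
#' standard protocol: 100 s windows stepping by 10 s at TR 2 s, alpha 0.05
#' with Bonferroni families of 24 (tdNCD time distances) and 264 (FC,
#' matching the parcellation size), and per-kind feature-selection
#' thresholds 0.001 (sFC) / 1e-5 (dFC) / 0.05 (tdNCD). Round-trips
#' unchanged through a YAML file.
#'
#' @param window_seconds,step_seconds,tr_seconds Sliding-window geometry.
#' @param alpha Family-wise error rate.
#' @param family_tdncd,family_fc Bonferroni family sizes.
#' @param selection_thresholds Named per-kind p-value cutoffs.
#' @param feature_kinds Feature kinds for classification.
#' @param model Classifier family (see [classifier_spec()]).
#' @param task Classification task.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param verbose Logical.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_seconds = 100, step_seconds = 10,
                       tr_seconds = 2, alpha = 0.05,
                       family_tdncd = 24, family_fc = 264,
                       selection_thresholds = default_selection_thresholds(),
                       feature_kinds = c("sfc_edge", "tdncd_roi_distance"),
                       model = "fcnet", task = "nc_vs_ad", seed = 1L,
                       out_dir = ".", verbose = TRUE) {
  structure(list(window_seconds = window_seconds,
                 step_seconds = step_seconds, tr_seconds = tr_seconds,
                 alpha = alpha, family_tdncd = family_tdncd,
                 family_fc = family_fc,
                 selection_thresholds = as.list(selection_thresholds),
                 feature_kinds = feature_kinds, model = model, task = task,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = verbose),
            class = "run_config")
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   invisibly returns `path`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[intersect(names(raw),
                                           names(formals(run_config)))])
  cfg
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
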