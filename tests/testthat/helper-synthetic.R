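# Shared fixture builders. Everything is generated in code at test time.

random_timeseries <- function(t_frames = 60, R = 5, seed = 1, tr = 2) {
  set.seed(seed)
  roi_timeseries(matrix(rnorm(t_frames * R), t_frames, R), tr_seconds = tr)
}

random_stack <- function(n_windows = 6, R = 5, seed = 1) {
  ts <- random_timeseries(t_frames = 20 + 5 * (n_windows - 1), R = R,
                          seed = seed)
  compute_dfc(ts, window_config(window_seconds = 40, step_seconds = 10,
                                tr_seconds = 2))
}

# A small multi-site cohort manifest with features generated directly
# (bypassing time-series simulation) for fast classification tests.
toy_classification_cohort <- function(n_sites = 4, n_per_group = 8,
                                      n_features = 30, separation = 0,
                                      seed = 1, with_mci = FALSE) {
  set.seed(seed)
  groups <- if (with_mci) c("NC", "MCI", "AD") else c("NC", "AD")
  man <- expand.grid(idx = seq_len(n_per_group), diagnosis = groups,
                     site_id = sprintf("site%d", seq_len(n_sites)),
                     stringsAsFactors = FALSE)
  man$subject_id <- sprintf("sub%03d", seq_len(nrow(man)))
  man$mmse <- round(pmin(30, pmax(0, rnorm(nrow(man),
    mean = c(NC = 28.5, MCI = 25, AD = 16.5)[man$diagnosis],
    sd = 2))))
  X <- matrix(rnorm(nrow(man) * n_features), nrow(man), n_features)
  if (separation > 0) {
    shift <- c(NC = 0, MCI = separation / 2, AD = separation)[man$diagnosis]
    X[, 1] <- X[, 1] + shift
  }
  rownames(X) <- man$subject_id
  colnames(X) <- sprintf("tdNCD_r%03d_d01", seq_len(n_features))
  attr(X, "kind") <- rep("tdncd_roi_distance", n_features)
  list(features = X, manifest = man[, c("subject_id", "site_id",
                                        "diagnosis", "mmse")])
}
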