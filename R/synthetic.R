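#' Specification for the multi-site synthetic cohort generator
#'
#' Describes a Markov state-switching Gaussian model of regional fMRI
#' dynamics. Regions are partitioned into networks and each latent
#' connectivity state is a factor model (one factor per network plus a
#' global factor) in which one network is dominantly coupled; the brain
#' switches states as a first-order Markov chain with a per-group dwell
#' probability. Group effects on reconfiguration are planted on
#' `affected_rois` with strength `effect_delta`: a positive direction
#' re-routes the region's factor loadings toward each state's dominant
#' network (amplifying profile reconfiguration, raising tdNCD), a negative
#' direction shrinks the region's loading contrast across states
#' (suppressing reconfiguration, lowering tdNCD). Sites differ in additive
#' white-noise level and global gain. MMSE scores are drawn from per-group
#' normals truncated to `[0, 30]`.
#'
#' The full-size defaults mirror a 7-site cohort of 809 subjects
#' (257 NC / 257 MCI / 295 AD) of 264-region series with 170 frames at
#' TR 2 s; desk-scale work typically sets `R = 40` and smaller group sizes.
#'
#' @param R Number of regions (default 264).
#' @param n_networks Number of network blocks (default 3, matching the
#'   number of states so every network takes a turn as the dominant block).
#' @param n_states Number of latent connectivity states (default 3).
#' @param dwell Named per-group probability of remaining in the current
#'   state at each frame (default 0.95 for all groups).
#' @param effect_delta Named per-group state-contrast scaling of affected
#'   regions (default NC 0, MCI 0.5, AD 1).
#' @param affected_rois Indices of regions carrying the planted effect
#'   (default: 5 evenly spaced regions).
#' @param affected_direction Signs (+1 raises reconfiguration, -1 lowers
#'   it), one per affected region (default `c(1, 1, 1, -1, -1)`).
#' @param n_sites Number of acquisition sites (default 7).
#' @param site_noise_sd Per-site additive noise SD (default ramps 0.3-0.6).
#' @param site_gain Per-site global gain (default ramps 0.9-1.1).
#' @param group_sizes `n_sites x 3` matrix of subjects per site and group
#'   (columns NC, MCI, AD); the default splits 257/257/295 as evenly as
#'   possible across 7 sites.
#' @param tr_seconds,t_frames Acquisition geometry (defaults 2 s, 170).
#' @param mmse_mean,mmse_sd Named per-group MMSE model (defaults
#'   NC 28.52/1.64, MCI 25.14/3.39, AD 16.56/6.02).
#' @param seed Master seed; every subject gets an independent stream keyed
#'   by (site, group, subject index).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(R = 264L, n_networks = 3L, n_states = 3L,
                           dwell = c(NC = 0.95, MCI = 0.95, AD = 0.95),
                           effect_delta = c(NC = 0, MCI = 0.5, AD = 1),
                           affected_rois = NULL,
                           affected_direction = c(1, 1, 1, -1, -1),
                           n_sites = 7L,
                           site_noise_sd = seq(0.3, 0.6, length.out = n_sites),
                           site_gain = seq(0.9, 1.1, length.out = n_sites),
                           group_sizes = NULL,
                           tr_seconds = 2, t_frames = 170L,
                           mmse_mean = c(NC = 28.52, MCI = 25.14, AD = 16.56),
                           mmse_sd = c(NC = 1.64, MCI = 3.39, AD = 6.02),
                           seed = 1L) {
  R <- as.integer(R)
  if (is.null(affected_rois))
    affected_rois <- unique(as.integer(round(seq(1, R, length.out = 5L))))
  affected_direction <- rep_len(affected_direction, length(affected_rois))
  if (is.null(group_sizes)) {
    split_even <- function(total) {
      base <- total %/% n_sites
      extra <- total %% n_sites
      base + as.integer(seq_len(n_sites) <= extra)
    }
    group_sizes <- cbind(NC = split_even(257L), MCI = split_even(257L),
                         AD = split_even(295L))
  }
  group_sizes <- as.matrix(group_sizes)
  colnames(group_sizes) <- c("NC", "MCI", "AD")
  stopifnot(all(dwell > 0 & dwell < 1),
            all(affected_rois >= 1L & affected_rois <= R),
            all(group_sizes >= 0), nrow(group_sizes) == n_sites,
            all(c("NC", "MCI", "AD") %in% names(dwell)),
            all(c("NC", "MCI", "AD") %in% names(effect_delta)))
  networks <- sort(rep(seq_len(n_networks), length.out = R))
  structure(list(R = R, n_networks = as.integer(n_networks),
                 n_states = as.integer(n_states), networks = networks,
                 dwell = dwell, effect_delta = effect_delta,
                 affected_rois = as.integer(affected_rois),
                 affected_direction = affected_direction,
                 n_sites = as.integer(n_sites),
                 site_noise_sd = rep_len(site_noise_sd, n_sites),
                 site_gain = rep_len(site_gain, n_sites),
                 group_sizes = group_sizes, tr_seconds = tr_seconds,
                 t_frames = as.integer(t_frames),
                 mmse_mean = mmse_mean, mmse_sd = mmse_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic cohort spec: %d ROIs, %d states, %d sites, %d subjects\n",
              x$R, x$n_states, x$n_sites, sum(x$group_sizes)))
  cat(sprintf("  planted effect on %d ROIs (delta: NC %g, MCI %g, AD %g)\n",
              length(x$affected_rois), x$effect_delta["NC"],
              x$effect_delta["MCI"], x$effect_delta["AD"]))
  invisible(x)
}

# Per-state factor loadings for one diagnosis group. Connectivity states
# are low-rank factor models: one latent factor per network plus a global
# factor, so every state covariance (loadings %*% t(loadings) + diagonal
# uniqueness) is positive definite by construction. In each state one
# network is dominant: its members load more strongly on their own factor
# and on the global factor, so every region's connectivity profile changes
# shape from state to state.
#
# The planted effect tunes how much an affected region's profile varies
# across states — exactly what tdNCD measures:
#   direction +1 re-routes the region's loadings toward the state's
#     dominant network with weight min(delta, 1), a large state-to-state
#     shape change that raises tdNCD;
#   direction -1 shrinks the region's loading contrast across states by
#     1 - delta (floored at 0), freezing its profile and lowering tdNCD.
state_loadings <- function(spec, diagnosis) {
  R <- spec$R; S <- spec$n_states; net <- spec$networks
  K <- spec$n_networks
  l_within <- sqrt(0.20)    # own-network loading, non-dominant state
  l_dominant <- sqrt(0.45)  # own-network loading when dominant
  g_base <- sqrt(0.05)      # global-factor loading
  g_dominant <- sqrt(0.20)  # global loading of dominant-network members
  base <- vector("list", S)
  doms <- ((seq_len(S) - 1L) %% K) + 1L
  for (s in seq_len(S)) {
    L <- matrix(0, R, K + 1L)
    for (k in seq_len(K)) {
      idx <- which(net == k)
      L[idx, k] <- if (k == doms[s]) l_dominant else l_within
      L[idx, K + 1L] <- if (k == doms[s]) g_dominant else g_base
    }
    base[[s]] <- L
  }
  delta <- spec$effect_delta[[diagnosis]]
  if (delta != 0 && length(spec$affected_rois) > 0L) {
    Lbar <- Reduce(`+`, base) / S
    for (s in seq_len(S)) {
      L <- base[[s]]
      for (j in seq_along(spec$affected_rois)) {
        a <- spec$affected_rois[j]
        if (spec$affected_direction[j] > 0) {
          w <- min(delta, 1)
          target <- numeric(K + 1L)
          target[doms[s]] <- l_dominant
          target[K + 1L] <- g_dominant
          L[a, ] <- (1 - w) * L[a, ] + w * target
        } else {
          shrink <- max(1 - delta, 0)
          L[a, ] <- Lbar[a, ] + shrink * (L[a, ] - Lbar[a, ])
        }
      }
      base[[s]] <- L
    }
  }
  base
}

# Full state correlation matrices (unit diagonal) from the factor loadings.
state_covariances <- function(spec, diagnosis) {
  lapply(state_loadings(spec, diagnosis), function(L) {
    Sig <- tcrossprod(L)
    diag(Sig) <- 1
    Sig
  })
}

# Cholesky factors with automatic diagonal loading if a planted
# perturbation leaves a state covariance indefinite.
state_chols <- function(spec, diagnosis) {
  lapply(state_covariances(spec, diagnosis), function(Sig) {
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    emin <- min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values)
    load <- abs(emin) + 1e-4
    message(sprintf("state covariance made positive definite by diagonal loading (%.3g)",
                    load))
    Sig2 <- stats::cov2cor(Sig + diag(load, nrow(Sig)))
    ch <- tryCatch(chol(Sig2), error = function(e) NULL)
    if (is.null(ch))
      stop("state covariance not positive definite even after loading")
    ch
  })
}

#' Simulate one subject's ROI time series
#'
#' Draws a first-order Markov state sequence with the group's dwell
#' probability, samples each frame from the current state's multivariate
#' normal, and applies the site's gain and additive white noise. The MMSE
#' score is drawn first from the group's truncated normal so that
#' manifest-only generation consumes the identical random stream.
#'
#' @param spec A [synthetic_spec()].
#' @param site_index Site number in `1..n_sites`.
#' @param diagnosis `"NC"`, `"MCI"` or `"AD"`.
#' @param seed Stream seed (typically derived from the master seed).
#' @param subject_id Identifier for the returned object.
#' @param chols Optional precomputed state Cholesky factors
#'   (from repeated calls within one group).
#' @return An [roi_timeseries()] object.
#' @export
simulate_subject <- function(spec, site_index, diagnosis, seed,
                             subject_id = "subject", chols = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"),
            site_index >= 1L, site_index <= spec$n_sites)
  if (is.null(chols)) chols <- state_chols(spec, diagnosis)
  Tn <- spec$t_frames; R <- spec$R; S <- spec$n_states
  dwell <- spec$dwell[[diagnosis]]
  with_seed(seed, {
    mmse <- round(min(30, max(0, stats::rnorm(1, spec$mmse_mean[[diagnosis]],
                                              spec$mmse_sd[[diagnosis]]))))
    st <- integer(Tn)
    st[1L] <- sample.int(S, 1L)
    u <- stats::runif(Tn)
    jump <- if (S > 1L) sample.int(S - 1L, Tn, replace = TRUE) else rep(1L, Tn)
    if (S == 1L) {
      st[] <- 1L
    } else {
      for (t in 2L:Tn) {
        if (u[t] <= dwell) st[t] <- st[t - 1L]
        else {
          others <- seq_len(S)[-st[t - 1L]]
          st[t] <- others[jump[t]]
        }
      }
    }
    Z <- matrix(stats::rnorm(Tn * R), Tn, R)
    X <- matrix(0, Tn, R)
    for (s in unique(st)) {
      rows <- which(st == s)
      X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
    }
    X <- spec$site_gain[site_index] * X +
      spec$site_noise_sd[site_index] * matrix(stats::rnorm(Tn * R), Tn, R)
    colnames(X) <- sprintf("ROI%03d", seq_len(R))
    roi_timeseries(X, subject_id = subject_id,
                   site_id = sprintf("site%d", site_index),
                   diagnosis = diagnosis, mmse = mmse,
                   tr_seconds = spec$tr_seconds)
  })
}

#' Generate a multi-site synthetic cohort
#'
#' Simulates every subject declared in the spec's `group_sizes`, either
#' in memory or as one TSV per subject plus a CSV manifest and a
#' ground-truth sidecar (the planted regions, directions, effect sizes,
#' dwell probabilities and seed — never read by the analysis pipeline).
#' Each subject has an independent random stream keyed by
#' (site, group, subject index), so the cohort is reproducible from
#' (spec, seed) and changing one group's size never perturbs other
#' subjects' data.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Optional output directory; when `NULL` the series are
#'   returned in memory.
#' @param manifest_only If `TRUE`, draw only the manifest (ids, sites,
#'   diagnoses, MMSE) without simulating any time series.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return A list of class `synthetic_cohort`: `manifest` (data frame with
#'   `subject_id`, `site_id`, `diagnosis`, `mmse`, `path`), `timeseries`
#'   (named list of [roi_timeseries()], unless `manifest_only` or writing
#'   to disk), `ground_truth`, `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, manifest_only = FALSE,
                            overwrite = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  writing <- !is.null(out_dir)
  if (writing) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
      stop("output directory ", out_dir,
           " is not empty; set overwrite = TRUE to proceed")
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  }
  groups <- c("NC", "MCI", "AD")
  rows <- list(); series <- list()
  for (si in seq_len(spec$n_sites)) {
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      n <- spec$group_sizes[si, g]
      if (n == 0L) next
      chols <- if (!manifest_only) state_chols(spec, g) else NULL
      for (k in seq_len(n)) {
        sid <- sprintf("s%02d_%s_%03d", si, g, k)
        sseed <- derive_seed(spec$seed, si, gi, k)
        if (manifest_only) {
          mmse <- with_seed(sseed, round(min(30, max(0,
            stats::rnorm(1, spec$mmse_mean[[g]], spec$mmse_sd[[g]])))))
          rows[[sid]] <- data.frame(subject_id = sid,
                                    site_id = sprintf("site%d", si),
                                    diagnosis = g, mmse = mmse,
                                    path = NA_character_)
          next
        }
        ts <- simulate_subject(spec, si, g, sseed, subject_id = sid,
                               chols = chols)
        path <- NA_character_
        if (writing) {
          path <- file.path(out_dir, paste0(sid, ".tsv"))
          write_timeseries(ts, path)
        } else {
          series[[sid]] <- ts
        }
        rows[[sid]] <- data.frame(subject_id = sid,
                                  site_id = sprintf("site%d", si),
                                  diagnosis = g, mmse = ts$mmse, path = path)
      }
    }
  }
  manifest <- if (length(rows) > 0L)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(subject_id = character(0), site_id = character(0),
                  diagnosis = character(0), mmse = numeric(0),
                  path = character(0))
  ground_truth <- list(affected_rois = spec$affected_rois,
                       affected_direction = spec$affected_direction,
                       effect_delta = as.list(spec$effect_delta),
                       dwell = as.list(spec$dwell), seed = spec$seed)
  if (writing) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    yaml::write_yaml(ground_truth, file.path(out_dir, "ground_truth.yaml"))
  }
  structure(list(manifest = manifest,
                 timeseries = if (!manifest_only && !writing) series else NULL,
                 ground_truth = ground_truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$manifest$diagnosis)
  cat(sprintf("synthetic cohort: %d subjects over %d sites (%s)\n",
              nrow(x$manifest), length(unique(x$manifest$site_id)),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}
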