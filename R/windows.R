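#' Sliding-window configuration
#'
#' Converts window and step lengths from seconds to frames given the
#' repetition time. With the defaults (window 100 s, step 10 s, TR 2 s) this
#' gives 50-frame windows advancing by 5 frames, so a 170-frame scan yields
#' 25 windows.
#'
#' @param window_seconds Window length in seconds (default 100).
#' @param step_seconds Step between consecutive window starts in seconds
#'   (default 10).
#' @param tr_seconds Seconds per frame (default 2).
#' @return An object of class `window_config` with elements
#'   `window_seconds`, `step_seconds`, `tr_seconds`, `window_frames`,
#'   `step_frames`.
#' @export
window_config <- function(window_seconds = 100, step_seconds = 10,
                          tr_seconds = 2) {
  stopifnot(window_seconds > 0, step_seconds > 0, tr_seconds > 0)
  wf <- as.integer(round(window_seconds / tr_seconds))
  sf <- as.integer(round(step_seconds / tr_seconds))
  if (wf < 3L)
    stop("window of ", wf, " frames is too short: Pearson correlation needs >= 3")
  if (sf < 1L) stop("step shorter than one frame")
  structure(list(window_seconds = window_seconds, step_seconds = step_seconds,
                 tr_seconds = tr_seconds, window_frames = wf,
                 step_frames = sf),
            class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("sliding windows: %g s (%d frames), step %g s (%d frames), TR %g s\n",
              x$window_seconds, x$window_frames, x$step_seconds, x$step_frames,
              x$tr_seconds))
  invisible(x)
}

#' Number of complete sliding windows in a series
#'
#' `floor((T - window_frames) / step_frames) + 1`; trailing frames that do
#' not fill a complete window are dropped.
#'
#' @param t_frames Number of frames in the series.
#' @param cfg A [window_config()].
#' @return Integer window count.
#' @export
count_windows <- function(t_frames, cfg) {
  stopifnot(inherits(cfg, "window_config"))
  if (cfg$window_frames > t_frames)
    stop(sprintf("window (%d frames) exceeds series length (%d frames)",
                 cfg$window_frames, t_frames))
  as.integer((t_frames - cfg$window_frames) %/% cfg$step_frames + 1L)
}

#' Frames retained after discarding equilibration volumes
#'
#' Scan duration divided by TR, minus the initial volumes discarded to allow
#' for magnetisation equilibrium. A 360 s scan at TR 2 s with 10 discarded
#' volumes retains 170 frames.
#'
#' @param scan_seconds Usable scan duration in seconds (default 360).
#' @param tr_seconds Seconds per frame (default 2).
#' @param discard_volumes Initial volumes dropped (default 10).
#' @return Integer number of retained frames.
#' @export
retained_frames <- function(scan_seconds = 360, tr_seconds = 2,
                            discard_volumes = 10) {
  stopifnot(scan_seconds > 0, tr_seconds > 0, discard_volumes >= 0)
  n <- as.integer(floor(scan_seconds / tr_seconds)) - as.integer(discard_volumes)
  if (n <= 0) stop("no frames left after discarding equilibration volumes")
  n
}
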