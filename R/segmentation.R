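# Windowed instantaneous-diffusion analysis: how diffusivity changes
# along a trajectory, three-state mobility categorization, and
# immobile-state dwell times.

#' Instantaneous-diffusion segmentation configuration
#'
#' @param window_s sliding window length, s (0.4 s default).
#' @param fast_threshold um^2/s; windows with D above this are "fast".
#' @param slow_threshold um^2/s; windows with D below this are
#'   "slow/immobile". In between is "medium".
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(window_s = 0.4, fast_threshold = 0.04,
                                slow_threshold = 0.01) {
  stop_if_not_scalar(window_s, "window_s", positive = TRUE)
  stop_if_not_scalar(fast_threshold, "fast_threshold", positive = TRUE)
  stop_if_not_scalar(slow_threshold, "slow_threshold", positive = TRUE)
  if (!(slow_threshold < fast_threshold))
    stop("slow_threshold must be < fast_threshold")
  structure(list(window_s = window_s, fast_threshold = fast_threshold,
                 slow_threshold = slow_threshold),
            class = "segmentation_config")
}

#' Windowed instantaneous diffusion along a trajectory
#'
#' Computes, for every window position (sliding by one frame), the MSD
#' of the windowed sub-trajectory, fits a diffusion coefficient with
#' the same adaptive linear-fit rule used for whole traces (no outlier
#' rejection at this scale), and assigns the window to one of three
#' mobility categories. The category is attached to the window's
#' midpoint frame; maximal runs of slow/immobile midpoints are merged
#' into dwell episodes whose duration spans from the start of the first
#' window of the run to the end of its last window (hence every dwell
#' lasts at least one window).
#'
#' Windows in which the majority of frames are interpolated rather than
#' measured are flagged.
#'
#' @param traj a [trajectory()].
#' @param cfg a [segmentation_config()].
#' @return object of class `state_track`: list with `windows`
#'   (data.frame: window_start_s, mid_time_s, D_inst, category,
#'   flagged) and `dwells` (data.frame: start_s, end_s, duration_s).
#' @export
instantaneous_diffusion <- function(traj, cfg = segmentation_config()) {
  traj <- as_trajectory(traj)
  dt <- frame_interval(traj)
  w <- max(2L, round(cfg$window_s / dt))
  if (w < 4L)
    stop("window must cover at least 4 frames at this frame interval")
  N <- nrow(traj)
  if (N <= w) stop("trajectory shorter than one window")
  x <- traj$x_um
  interp <- traj$interpolated
  n_win <- N - w + 1L
  rules <- refinement_rules(d_max = Inf, r2_min = 0, p_max = 0.05)
  D <- numeric(n_win); flagged <- logical(n_win)
  for (s in seq_len(n_win)) {
    seg <- x[s:(s + w - 1L)]
    sub <- trajectory(seg, dt, id = "window")
    D[s] <- fit_diffusion_coefficient(compute_msd(sub), rules)$D_um2_s
    flagged[s] <- mean(interp[s:(s + w - 1L)]) > 0.5
  }
  category <- ifelse(D > cfg$fast_threshold, "fast",
                     ifelse(D < cfg$slow_threshold, "slow/immobile",
                            "medium"))
  mid <- (seq_len(n_win) - 1L) + (w %/% 2L)
  windows <- data.frame(window_start_s = traj$time_s[seq_len(n_win)],
                        mid_time_s = traj$time_s[mid + 1L],
                        D_inst = D, category = category,
                        flagged = flagged)
  slow <- category == "slow/immobile"
  dwells <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       duration_s = numeric(0))
  if (any(slow)) {
    r <- rle(slow)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      t0 <- windows$window_start_s[starts[k]]
      t1 <- windows$window_start_s[ends[k]] + w * dt
      dwells <- rbind(dwells, data.frame(start_s = t0, end_s = t1,
                                         duration_s = t1 - t0))
    }
  }
  structure(list(windows = windows, dwells = dwells, config = cfg,
                 frame_interval = dt, window_frames = w),
            class = "state_track")
}

#' Mobility-state occupancy fractions
#'
#' @param track a `state_track` from [instantaneous_diffusion()].
#' @return named numeric vector (fast, medium, slow/immobile) summing
#'   to 1.
#' @export
state_occupancy <- function(track) {
  stopifnot(inherits(track, "state_track"))
  cats <- c("fast", "medium", "slow/immobile")
  counts <- table(factor(track$windows$category, levels = cats))
  as.numeric(counts) / sum(counts) -> frac
  stats::setNames(frac, cats)
}
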