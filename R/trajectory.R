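# Trajectory: uniformly sampled 1D positions of a single particle.

#' Construct a trajectory
#'
#' A trajectory is a uniformly sampled series of 1D positions (um) of one
#' particle along the DNA axis. All downstream MSD machinery assumes the
#' uniform spacing enforced here.
#'
#' @param x_um positions, um.
#' @param frame_interval time between samples, s.
#' @param t0 time of the first sample, s.
#' @param id source identifier (trace id).
#' @param interpolated logical vector flagging positions filled in by
#'   interpolation rather than fitted from data.
#' @return object of class `trajectory`: data.frame with columns
#'   `frame`, `time_s`, `x_um`, `interpolated`, plus attributes
#'   `frame_interval` and `id`.
#' @export
trajectory <- function(x_um, frame_interval, t0 = 0, id = "trace",
                       interpolated = NULL) {
  x_um <- as.numeric(x_um)
  if (length(x_um) < 2L) stop("a trajectory needs >= 2 positions")
  if (any(!is.finite(x_um))) stop("positions must be finite")
  stop_if_not_scalar(frame_interval, "frame_interval", positive = TRUE)
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(x_um))
  stopifnot(length(interpolated) == length(x_um))
  out <- data.frame(
    frame = seq_along(x_um) - 1L,
    time_s = t0 + (seq_along(x_um) - 1L) * frame_interval,
    x_um = x_um,
    interpolated = as.logical(interpolated)
  )
  structure(out, class = c("trajectory", "data.frame"),
            frame_interval = frame_interval, id = as.character(id))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames @ %g s, span %.3f-%.3f um>\n",
              attr(x, "id"), nrow(x), attr(x, "frame_interval"),
              min(x$x_um), max(x$x_um)))
  invisible(x)
}

frame_interval <- function(traj) attr(traj, "frame_interval")

as_trajectory <- function(df, frame_interval = NULL, id = "trace") {
  if (inherits(df, "trajectory")) return(df)
  if (is.null(frame_interval)) {
    dt <- diff(df$time_s)
    if (length(dt) < 1L || diff(range(dt)) > 1e-9 * max(abs(dt)))
      stop("non-uniform time sampling; supply frame_interval explicitly")
    frame_interval <- dt[1L]
  }
  trajectory(df$x_um, frame_interval,
             t0 = if ("time_s" %in% names(df)) df$time_s[1L] else 0,
             id = id,
             interpolated = if ("interpolated" %in% names(df))
               df$interpolated else NULL)
}
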