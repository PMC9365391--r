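# Dual-color roadblock analysis: pair a mobile-particle trajectory with
# a (nearly) stationary roadblock and classify every encounter as
# reflected, stuck, or crossover.

#' Extend a roadblock trajectory past photobleaching
#'
#' Roadblocks such as dCas9 stay bound long after their dye bleaches,
#' so their position remains usable: the trace is extended at the mean
#' of the observed positions out to `n_frames` total frames.
#'
#' @param roadblock a [trajectory()] of the roadblock while visible.
#' @param n_frames length of the full shared timebase, frames.
#' @return a [trajectory()] of `n_frames` positions; extension frames
#'   are flagged `interpolated`.
#' @export
extend_after_bleach <- function(roadblock, n_frames) {
  roadblock <- as_trajectory(roadblock)
  if (nrow(roadblock) < 5L)
    stop("need at least 5 observed roadblock positions")
  n_frames <- as.integer(n_frames)
  if (n_frames <= nrow(roadblock)) return(roadblock)
  n_ext <- n_frames - nrow(roadblock)
  trajectory(c(roadblock$x_um, rep(mean(roadblock$x_um), n_ext)),
             frame_interval(roadblock), t0 = roadblock$time_s[1],
             id = attr(roadblock, "id"),
             interpolated = c(roadblock$interpolated, rep(TRUE, n_ext)))
}

#' Classify mobile-particle / roadblock encounters
#'
#' An encounter opens when the mobile particle enters within `radius`
#' of the roadblock position (the mean of the roadblock trace, which
#' must be effectively stationary) and closes when it leaves again.
#' Classification: crossover if it exits on the opposite side from the
#' one it entered on; stuck if it remains inside for at least
#' `stuck_min_duration` or until the trace ends; reflected otherwise
#' (exits the entry side quickly).
#'
#' @param mobile a [trajectory()] of the diffusing particle.
#' @param roadblock a [trajectory()] of the roadblock, or a single
#'   position (um).
#' @param radius colocalization radius, um. Default 0.164 um = twice
#'   the 82 nm localization precision.
#' @param stuck_min_duration s; residence at least this long counts as
#'   stuck even if the particle later escapes.
#' @param censored_at_end what to call an encounter still open when the
#'   trace ends with residence below `stuck_min_duration`: `"stuck"`
#'   (default; particles seen at the roadblock through the end of the
#'   trace are scored stuck) or `"exclude"` (treat as right-censored
#'   and drop from the event list and fractions — the statistically
#'   neutral choice for closed-loop recovery, since a trace can end
#'   while any type of encounter is in progress). Encounters that reach
#'   `stuck_min_duration` are stuck either way.
#' @return object of class `encounter_set`: list with `events`
#'   (data.frame: start_s, end_s, duration_s, entry_side,
#'   classification) and `fractions` (named, summing to 1 when events
#'   exist).
#' @export
classify_encounters <- function(mobile, roadblock, radius = 0.164,
                                stuck_min_duration = 2,
                                censored_at_end = c("stuck", "exclude")) {
  censored_at_end <- match.arg(censored_at_end)
  mobile <- as_trajectory(mobile)
  stop_if_not_scalar(radius, "radius", positive = TRUE)
  if (is.numeric(roadblock) && length(roadblock) == 1L) {
    rb_pos <- roadblock
  } else {
    roadblock <- as_trajectory(roadblock)
    obs <- roadblock$x_um[!roadblock$interpolated]
    if (stats::sd(obs) > radius)
      stop("roadblock is mobile beyond the colocalization radius")
    rb_pos <- mean(obs)
  }
  dt <- frame_interval(mobile)
  x <- mobile$x_um
  inside <- abs(x - rb_pos) <= radius
  ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                   duration_s = numeric(0), entry_side = numeric(0),
                   classification = character(0))
  if (any(inside)) {
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      entry_side <- if (i0 > 1L) sign(x[i0 - 1L] - rb_pos)
                    else sign(x[i0] - rb_pos)
      if (entry_side == 0) entry_side <- 1
      at_end <- i1 == length(x)
      duration <- (i1 - i0 + 1L) * dt
      # residence past the stuck threshold (or to trace end) wins even
      # if the particle later escapes on the far side
      cls <- if (duration >= stuck_min_duration) "stuck"
      else if (at_end) {
        if (censored_at_end == "stuck") "stuck" else NA_character_
      } else {
        exit_side <- sign(x[i1 + 1L] - rb_pos)
        if (exit_side != 0 && exit_side != entry_side) "crossover"
        else "reflected"
      }
      if (is.na(cls)) next
      ev <- rbind(ev, data.frame(start_s = mobile$time_s[i0],
                                 end_s = mobile$time_s[i1],
                                 duration_s = duration,
                                 entry_side = entry_side,
                                 classification = cls))
    }
  }
  cats <- c("reflected", "stuck", "crossover")
  frac <- if (nrow(ev))
    as.numeric(table(factor(ev$classification, levels = cats))) / nrow(ev)
  else rep(NA_real_, 3)
  structure(list(events = ev,
                 fractions = stats::setNames(frac, cats),
                 roadblock_position_um = rb_pos, radius_um = radius),
            class = "encounter_set")
}

#' @export
print.encounter_set <- function(x, ...) {
  cat(sprintf("<%d encounters at %.3f um: %s>\n", nrow(x$events),
              x$roadblock_position_um,
              paste(sprintf("%s %.1f%%", names(x$fractions),
                            100 * x$fractions), collapse = ", ")))
  invisible(x)
}
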