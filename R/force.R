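# Nucleosome counting from force-extension curves: detection of
# discrete unwrapping steps in the 15-30 pN window and the 5 pN
# compaction relation.

#' Detect nucleosome-unwrapping steps in a force-extension curve
#'
#' Scans the rising-force segment inside `force_window` with a
#' two-sided sliding-mean jump statistic (difference of the means of
#' the next and previous `half_window` samples). Contiguous runs where
#' the statistic exceeds `min_step_nm` become events. Each event's size
#' is measured as the difference of median distance levels in the
#' windows just outside the run (clipped at neighbouring events), minus
#' a robust estimate of the smooth baseline drift across the event —
#' so an event that actually contains several near-coincident
#' unwrapping steps measures their summed jump. Events are therefore
#' assigned a multiplicity `round(size / ref)`, `ref` being the median
#' event size, and `n_steps` is the sum of multiplicities.
#'
#' A collapse of force to near zero inside the rising segment is a
#' broken tether; analysis is truncated there and flagged.
#'
#' @param curve a `force_extension` data.frame (columns force_pN,
#'   distance_um and optionally segment).
#' @param force_window pN window in which unwrapping is scored.
#' @param min_step_nm smallest jump accepted as a step (default 15 nm,
#'   ~60% of a canonical 25 nm inner-turn step).
#' @param half_window samples per side of the sliding mean.
#' @return list with `events` (data.frame: index, force_pN, size_nm,
#'   multiplicity), `n_steps`, `mean_step_nm`, `tether_break`.
#' @export
detect_unwrapping_steps <- function(curve, force_window = c(15, 30),
                                    min_step_nm = 15, half_window = 20) {
  stopifnot(is.data.frame(curve),
            all(c("force_pN", "distance_um") %in% names(curve)))
  seg <- if ("segment" %in% names(curve)) curve$segment == "up"
         else rep(TRUE, nrow(curve))
  up <- curve[seg, , drop = FALSE]
  if (max(up$force_pN) < force_window[1])
    stop("curve does not reach the unwrapping force window")

  tether_break <- FALSE
  drops <- which(diff(up$force_pN) < -5)
  if (length(drops)) {
    tether_break <- TRUE
    up <- up[seq_len(drops[1]), , drop = FALSE]
  }

  k <- half_window
  no_events <- list(events = data.frame(index = integer(0),
                                        force_pN = numeric(0),
                                        size_nm = numeric(0),
                                        multiplicity = integer(0)),
                    n_steps = 0L, mean_step_nm = NA_real_,
                    tether_break = tether_break)
  sel <- which(up$force_pN >= force_window[1] - 0.5 &
               up$force_pN <= force_window[2] + 0.5)
  if (length(sel) < 2 * k + 2) return(no_events)
  d <- up$distance_um[sel] * 1000  # nm
  f <- up$force_pN[sel]
  n <- length(d)
  jump <- rep(-Inf, n)
  cs <- c(0, cumsum(d))
  ii <- seq.int(k + 1L, n - k)
  jump[ii] <- (cs[ii + k + 1L] - cs[ii + 1L]) / k -
    (cs[ii + 1L] - cs[ii - k + 1L]) / k
  hit <- jump >= min_step_nm
  if (!any(hit)) return(no_events)

  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev_start <- starts[r$values]; ev_end <- ends[r$values]
  # a single step can split into two runs when the statistic dips at
  # its shoulder; runs closer than one smoothing window are one event
  if (length(ev_start) > 1L) {
    keep_s <- ev_start[1]; ms <- integer(0); me <- integer(0)
    cur_s <- ev_start[1]; cur_e <- ev_end[1]
    for (g in seq_along(ev_start)[-1]) {
      if (ev_start[g] - cur_e <= k) {
        cur_e <- ev_end[g]
      } else {
        ms <- c(ms, cur_s); me <- c(me, cur_e)
        cur_s <- ev_start[g]; cur_e <- ev_end[g]
      }
    }
    ev_start <- c(ms, cur_s); ev_end <- c(me, cur_e)
  }
  n_ev <- length(ev_start)

  # smooth baseline drift (nm/sample): least-squares slope within each
  # quiet inter-event stretch (no steps inside a stretch), pooled with
  # length weights. Precision matters here: the correction is
  # slope * span, so a 0.1 nm/sample error would bias every event size
  # by several nm in the same direction.
  quiet <- rep(TRUE, n)
  for (g in seq_len(n_ev))
    quiet[max(1, ev_start[g] - k):min(n, ev_end[g] + k)] <- FALSE
  qr <- rle(quiet)
  q_end <- cumsum(qr$lengths); q_start <- q_end - qr$lengths + 1L
  sl <- numeric(0); wt <- numeric(0)
  for (q in which(qr$values & qr$lengths >= 30L)) {
    ii <- q_start[q]:q_end[q]
    f0 <- linfit(ii, d[ii])
    if (is.finite(f0$slope)) { sl <- c(sl, f0$slope); wt <- c(wt, length(ii)) }
  }
  slope <- if (length(sl)) sum(sl * wt) / sum(wt) else 0

  events <- data.frame(index = integer(0), force_pN = numeric(0),
                       size_nm = numeric(0))
  for (g in seq_len(n_ev)) {
    lo_min <- if (g > 1) ev_end[g - 1] + 1L else 1L
    hi_max <- if (g < n_ev) ev_start[g + 1] - 1L else n
    before <- seq.int(max(lo_min, ev_start[g] - 3L * k), ev_start[g] - 1L)
    after <- seq.int(ev_end[g] + 1L, min(hi_max, ev_end[g] + 3L * k))
    if (!length(before) || !length(after)) next
    span <- mean(after) - mean(before)
    size <- stats::median(d[after]) - stats::median(d[before]) -
      slope * span
    peak <- (ev_start[g]:ev_end[g])[which.max(jump[ev_start[g]:ev_end[g]])]
    events <- rbind(events, data.frame(index = sel[peak],
                                       force_pN = f[peak],
                                       size_nm = size))
  }
  # events whose measured level change is under half the detection
  # threshold are statistic artifacts (e.g. run splits), not steps
  events <- events[events$size_nm >= min_step_nm / 2, , drop = FALSE]
  if (!nrow(events)) return(no_events)
  ref <- stats::median(events$size_nm[events$size_nm >= min_step_nm])
  if (!is.finite(ref)) ref <- stats::median(events$size_nm)
  mult <- pmax(1L, as.integer(round(events$size_nm / ref)))
  # refine the unit-step reference with the provisional multiplicities
  # (a curve with several merged events drags the plain median down)
  ref <- stats::median(events$size_nm / mult)
  events$multiplicity <- pmax(1L, as.integer(round(events$size_nm / ref)))
  list(events = events,
       n_steps = sum(events$multiplicity),
       mean_step_nm = mean(events$size_nm / events$multiplicity),
       tether_break = tether_break)
}

#' Tether length at a given force
#'
#' Interpolates the distance at the first crossing of `force_pN` within
#' the requested monotone segment of the curve.
#'
#' @param curve a `force_extension` data.frame.
#' @param force_pN force at which to read the length (default 5 pN).
#' @param segment `"up"` or `"down"`.
#' @return length, um.
#' @export
length_at_force <- function(curve, force_pN = 5, segment = "up") {
  stopifnot(is.data.frame(curve))
  sub <- if ("segment" %in% names(curve))
    curve[curve$segment == segment, , drop = FALSE] else curve
  if (!nrow(sub)) stop("requested segment not present")
  if (force_pN < min(sub$force_pN) || force_pN > max(sub$force_pN))
    stop("force outside the segment's range")
  stats::approx(sub$force_pN, sub$distance_um, xout = force_pN,
                ties = mean)$y
}

#' Count nucleosomes from the 5 pN compaction relation
#'
#' Each unwrapped nucleosome lengthens the array held at 5 pN by
#' `per_nuc_nm` (34.6 nm), so the count is the rounded ratio of the
#' before/after length difference to that increment.
#'
#' @param length_5pN_before_um array length at 5 pN before unwrapping,
#'   um.
#' @param length_5pN_after_um array length at 5 pN after unwrapping,
#'   um.
#' @param per_nuc_nm lengthening per nucleosome, nm.
#' @return integer count.
#' @export
count_by_compaction <- function(length_5pN_before_um,
                                length_5pN_after_um,
                                per_nuc_nm = 34.6) {
  stop_if_not_scalar(length_5pN_before_um, "length_5pN_before_um",
                     positive = TRUE)
  stop_if_not_scalar(length_5pN_after_um, "length_5pN_after_um",
                     positive = TRUE)
  if (length_5pN_after_um < length_5pN_before_um)
    stop("length after unwrapping must be >= length before")
  as.integer(round((length_5pN_after_um - length_5pN_before_um) * 1000 /
                     per_nuc_nm))
}

#' Count nucleosomes on an up/down force-extension curve
#'
#' Convenience wrapper: detects unwrapping steps on the rising segment
#' and counts by compaction from the 5 pN lengths of the rising
#' (wrapped) and falling (unwrapped) segments.
#'
#' @param curve a `force_extension` with both "up" and "down" segments.
#' @param per_nuc_nm lengthening per nucleosome at 5 pN, nm.
#' @param ... passed to [detect_unwrapping_steps()].
#' @return list with `n_steps`, `n_compaction`, `mean_step_nm`,
#'   `length_5pN_before_um`, `length_5pN_after_um`, `steps` (the full
#'   detector output).
#' @export
count_nucleosomes <- function(curve, per_nuc_nm = 34.6, ...) {
  steps <- detect_unwrapping_steps(curve, ...)
  before <- length_at_force(curve, 5, "up")
  after <- length_at_force(curve, 5, "down")
  list(n_steps = steps$n_steps,
       n_compaction = count_by_compaction(before, after, per_nuc_nm),
       mean_step_nm = steps$mean_step_nm,
       length_5pN_before_um = before,
       length_5pN_after_um = after,
       steps = steps)
}

#' Mean internucleosome spacing on a tether
#'
#' Reports the tether length divided both by the number of gaps
#' (n + 1, nucleosomes strictly interior) and by the nucleosome count
#' itself; which divisor applies depends on whether the array ends are
#' counted as gaps.
#'
#' @param tether_length_um tether length, um.
#' @param n_nucleosomes nucleosome count.
#' @return list with `spacing_gaps_um` (= L/(n+1)) and
#'   `spacing_per_nuc_um` (= L/n).
#' @export
internucleosome_spacing <- function(tether_length_um, n_nucleosomes) {
  stop_if_not_scalar(tether_length_um, "tether_length_um", positive = TRUE)
  stop_if_not_scalar(n_nucleosomes, "n_nucleosomes", positive = TRUE)
  list(spacing_gaps_um = tether_length_um / (n_nucleosomes + 1),
       spacing_per_nuc_um = tether_length_um / n_nucleosomes)
}
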