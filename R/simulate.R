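# Synthetic-data generators: Brownian 1D trajectories with reflecting
# boundaries and probabilistic roadblocks, photon-noise kymographs,
# binding-event streams, and force-extension curves with discrete
# nucleosome-unwrapping steps. Every downstream analysis stage is
# validated closed-loop against these generators.

#' Simulation configuration for a 1D Brownian trajectory
#'
#' @param D_true diffusion coefficient, um^2/s.
#' @param frame_interval sampling interval, s (confocal line time).
#' @param n_frames number of samples.
#' @param x0 starting position, um.
#' @param boundaries ordered positions of reflecting walls, um (possibly
#'   empty). The particle is confined to the interval of walls that
#'   brackets `x0`; it can never cross a wall.
#' @param roadblocks list of point obstacles, each
#'   `list(position =, p_reflect =, p_stick =, p_cross =)` with the
#'   three probabilities summing to 1.
#' @param bleach_rate photobleaching rate, 1/s (0 = never).
#' @param unbind_rate dissociation rate, 1/s (0 = never).
#' @param encounter_radius half-width of the roadblock interaction zone,
#'   um; default one localization sigma (82 nm). A new outcome is drawn
#'   each time the particle enters this zone (one draw per encounter
#'   episode, not per frame).
#' @param stuck_mean mean of the exponential stuck time for "stick"
#'   outcomes, s. `Inf` (default) pins the particle for the remainder of
#'   the trace, matching stuck-for-trace-duration events.
#' @param seed integer RNG seed, or NULL to use the current RNG stream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(D_true, frame_interval, n_frames, x0 = 0,
                       boundaries = numeric(0), roadblocks = list(),
                       bleach_rate = 0, unbind_rate = 0,
                       encounter_radius = 0.082, stuck_mean = Inf,
                       seed = NULL) {
  stop_if_not_scalar(D_true, "D_true", nonnegative = TRUE)
  stop_if_not_scalar(frame_interval, "frame_interval", positive = TRUE)
  stop_if_not_scalar(n_frames, "n_frames", positive = TRUE)
  stop_if_not_scalar(x0, "x0")
  stop_if_not_scalar(bleach_rate, "bleach_rate", nonnegative = TRUE)
  stop_if_not_scalar(unbind_rate, "unbind_rate", nonnegative = TRUE)
  stop_if_not_scalar(encounter_radius, "encounter_radius", positive = TRUE)
  if (length(boundaries)) {
    boundaries <- as.numeric(boundaries)
    if (any(!is.finite(boundaries)) || is.unsorted(boundaries, strictly = TRUE))
      stop("'boundaries' must be finite and strictly increasing")
  }
  for (rb in roadblocks) {
    p <- c(rb$p_reflect, rb$p_stick, rb$p_cross)
    if (length(p) != 3 || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-9)
      stop("roadblock probabilities must lie in [0,1] and sum to 1")
    stop_if_not_scalar(rb$position, "roadblock position")
  }
  structure(list(D_true = D_true, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), x0 = x0,
                 boundaries = boundaries, roadblocks = roadblocks,
                 bleach_rate = bleach_rate, unbind_rate = unbind_rate,
                 encounter_radius = encounter_radius,
                 stuck_mean = stuck_mean, seed = seed),
            class = "sim_config")
}

# Reflect x into [lo, hi] (elastic fold-back, possibly repeated for
# large overshoots).
reflect_into <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + pmin(y, 2 * L - y)
}

# Interval of cfg$boundaries bracketing x0; c(-Inf, Inf) when
# unconfined on that side.
bracketing_interval <- function(boundaries, x0) {
  if (!length(boundaries)) return(c(-Inf, Inf))
  lo <- suppressWarnings(max(boundaries[boundaries <= x0], -Inf))
  hi <- suppressWarnings(min(boundaries[boundaries >= x0], Inf))
  if (lo == hi) stop("x0 sits exactly on a reflecting wall")
  c(lo, hi)
}

#' Simulate a 1D Brownian trajectory with boundaries and roadblocks
#'
#' Gaussian increments of variance `2 * D_true * frame_interval`;
#' reflecting walls handled by elastic fold-back of the overshoot.
#' Roadblock interactions are drawn once per encounter episode: when the
#' particle enters within `encounter_radius` of a roadblock an outcome
#' (reflect / stick / cross) is drawn and enforced until the particle
#' leaves the zone again. "Reflect" makes the roadblock a hard wall for
#' the episode, "stick" pins the particle at the roadblock for an
#' exponential stuck time (by default until the trace ends), "cross"
#' removes the obstacle behind the particle so that it exits on the far
#' side. The realized outcome therefore matches the drawn one, mirroring
#' per-event classification of roadblock encounters.
#'
#' The observable lifetime is the minimum of independent exponential
#' photobleaching and unbinding times; frames after it are flagged dead.
#'
#' @param cfg a [sim_config()].
#' @return object of class `ground_truth`: list with `trajectory` (the
#'   alive portion as a [trajectory()], or NULL if fewer than 2 frames
#'   survive), `x_um`/`time_s`/`alive` over the full frame grid,
#'   `events` (roadblock interaction log), `D_true`,
#'   `interval_length_um` and the config.
#' @export
simulate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_frames
    dt <- cfg$frame_interval
    sd_step <- sqrt(2 * cfg$D_true * dt)
    iv <- bracketing_interval(cfg$boundaries, cfg$x0)

    total_rate <- cfg$bleach_rate + cfg$unbind_rate
    lifetime <- if (total_rate > 0) stats::rexp(1, rate = total_rate) else Inf
    times <- (seq_len(n) - 1L) * dt
    alive <- times < lifetime

    events <- data.frame(time_s = numeric(0), roadblock = integer(0),
                         outcome = character(0))
    if (!length(cfg$roadblocks) && cfg$D_true >= 0) {
      # fast path: free or boundary-only motion; reflection applied as a
      # pathwise fold of the free walk (distribution-exact)
      incr <- stats::rnorm(n - 1L, 0, sd_step)
      x <- cfg$x0 + c(0, cumsum(incr))
      if (is.finite(iv[1]) || is.finite(iv[2])) {
        if (is.finite(iv[1]) && is.finite(iv[2])) {
          x <- reflect_into(x, iv[1], iv[2])
        } else if (is.finite(iv[1])) {
          x <- iv[1] + abs(x - iv[1])
        } else {
          x <- iv[2] - abs(x - iv[2])
        }
      }
    } else {
      x <- numeric(n)
      x[1] <- cfg$x0
      rbs <- cfg$roadblocks
      nrb <- length(rbs)
      ep_active <- rep(FALSE, nrb)
      ep_outcome <- character(nrb)
      ep_side <- numeric(nrb)
      stuck_until <- rep(-Inf, nrb)
      eps <- cfg$encounter_radius
      for (i in seq_len(n)[-1]) {
        prev <- x[i - 1L]
        cand <- prev + stats::rnorm(1, 0, sd_step)
        if (is.finite(iv[1]) && is.finite(iv[2])) {
          cand <- reflect_into(cand, iv[1], iv[2])
        } else if (is.finite(iv[1])) {
          cand <- iv[1] + abs(cand - iv[1])
        } else if (is.finite(iv[2])) {
          cand <- iv[2] - abs(cand - iv[2])
        }
        t_now <- times[i]
        for (k in seq_len(nrb)) {
          pos <- rbs[[k]]$position
          if (ep_active[k]) {
            oc <- ep_outcome[k]
            if (oc == "stick") {
              if (t_now < stuck_until[k]) {
                cand <- pos
              } else if (abs(cand - pos) > eps) {
                ep_active[k] <- FALSE
              }
            } else if (oc == "reflect") {
              # roadblock is a hard wall on the entry side
              if (sign(cand - pos) != ep_side[k] && cand != pos)
                cand <- 2 * pos - cand
              if (abs(cand - pos) > eps) ep_active[k] <- FALSE
            } else { # cross: wall behind the particle at the zone edge
              edge <- pos + ep_side[k] * eps
              if (sign(cand - edge) == ep_side[k] && cand != edge)
                cand <- 2 * edge - cand
              if (abs(cand - pos) > eps) ep_active[k] <- FALSE
            }
          } else if (abs(cand - pos) <= eps) {
            p <- c(rbs[[k]]$p_reflect, rbs[[k]]$p_stick, rbs[[k]]$p_cross)
            oc <- sample(c("reflect", "stick", "cross"), 1L, prob = p)
            side <- sign(prev - pos)
            if (side == 0) side <- if (cand >= pos) 1 else -1
            ep_active[k] <- TRUE
            ep_outcome[k] <- oc
            ep_side[k] <- side
            events <- rbind(events, data.frame(time_s = t_now,
                                               roadblock = k,
                                               outcome = oc))
            if (oc == "stick") {
              stuck_until[k] <- t_now +
                if (is.finite(cfg$stuck_mean))
                  stats::rexp(1, 1 / cfg$stuck_mean) else Inf
              cand <- pos
            } else if (oc == "reflect") {
              if (sign(cand - pos) != side && cand != pos)
                cand <- 2 * pos - cand
            }
          }
        }
        x[i] <- cand
      }
    }

    traj <- NULL
    n_alive <- sum(alive)
    if (n_alive >= 2L)
      traj <- trajectory(x[seq_len(n_alive)], dt, id = "sim")
    structure(list(trajectory = traj, x_um = x, time_s = times,
                   alive = alive, events = events, D_true = cfg$D_true,
                   interval_length_um = if (all(is.finite(iv)))
                     diff(iv) else Inf,
                   config = cfg),
              class = "ground_truth")
  })
}

#' Add Gaussian localization noise to a trajectory
#'
#' Models the finite localization precision of centroid tracking as
#' i.i.d. Gaussian noise on every position.
#'
#' @param traj a [trajectory()] or `ground_truth`.
#' @param sigma_um noise standard deviation, um (82 nm default, the
#'   photon-budget prediction for the confocal conditions emulated
#'   here).
#' @param seed optional RNG seed.
#' @return a [trajectory()] with perturbed positions.
#' @export
add_localization_noise <- function(traj, sigma_um = 0.082, seed = NULL) {
  if (inherits(traj, "ground_truth")) traj <- traj$trajectory
  stopifnot(inherits(traj, "trajectory"))
  stop_if_not_scalar(sigma_um, "sigma_um", nonnegative = TRUE)
  with_seed(seed, {
    trajectory(traj$x_um + stats::rnorm(nrow(traj), 0, sigma_um),
               frame_interval(traj), t0 = traj$time_s[1],
               id = attr(traj, "id"), interpolated = traj$interpolated)
  })
}

#' Kymograph container
#'
#' @param counts non-negative integer matrix, `n_pixels x n_lines`
#'   (rows = space, columns = scan lines/time).
#' @param pixel_size_um pixel size, um.
#' @param line_time_s time per scan line, s.
#' @return object of class `kymograph`.
#' @export
kymograph <- function(counts, pixel_size_um, line_time_s) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  stop_if_not_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stop_if_not_scalar(line_time_s, "line_time_s", positive = TRUE)
  structure(list(counts = counts, pixel_size_um = pixel_size_um,
                 line_time_s = line_time_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph: %d px x %d lines, a = %g um, dt = %g s>\n",
              nrow(x$counts), ncol(x$counts), x$pixel_size_um,
              x$line_time_s))
  invisible(x)
}

#' Kymograph rendering parameters
#'
#' Defaults emulate confocal line scanning of a single Cy3 dye: 100 nm
#' pixels, a 294 nm PSF, 12.9 signal photons and 0.8 background photons
#' per 5-pixel window per line.
#'
#' @param pixel_size_um pixel size, um.
#' @param psf_sigma_um PSF standard deviation, um.
#' @param photons_mean expected signal photons per line per particle.
#' @param background_mean expected background photons per 5-pixel window
#'   per line.
#' @param n_pixels number of pixels per scan line.
#' @param seed optional RNG seed.
#' @return object of class `kymograph_spec`.
#' @export
kymograph_spec <- function(pixel_size_um = 0.1, psf_sigma_um = 0.294,
                           photons_mean = 12.9, background_mean = 0.8,
                           n_pixels = 64, seed = NULL) {
  stop_if_not_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stop_if_not_scalar(psf_sigma_um, "psf_sigma_um", positive = TRUE)
  stop_if_not_scalar(photons_mean, "photons_mean", nonnegative = TRUE)
  stop_if_not_scalar(background_mean, "background_mean", nonnegative = TRUE)
  stop_if_not_scalar(n_pixels, "n_pixels", positive = TRUE)
  structure(list(pixel_size_um = pixel_size_um,
                 psf_sigma_um = psf_sigma_um,
                 photons_mean = photons_mean,
                 background_mean = background_mean,
                 n_pixels = as.integer(n_pixels), seed = seed),
            class = "kymograph_spec")
}

#' Render a trajectory into a photon-count kymograph
#'
#' Per scan line, a Poisson number of signal photons is drawn and each
#' photon's detected position sampled from a Gaussian of width
#' `psf_sigma_um` centred on the true particle position, then binned
#' into pixels; background counts are Poisson with mean
#' `background_mean / 5` per pixel. Counts are integers, as from a
#' photon-counting detector.
#'
#' @param gt a `ground_truth` or [trajectory()].
#' @param spec a [kymograph_spec()].
#' @return a [kymograph()].
#' @export
render_kymograph <- function(gt, spec = kymograph_spec()) {
  traj <- if (inherits(gt, "ground_truth")) gt$trajectory else gt
  stopifnot(inherits(traj, "trajectory"), inherits(spec, "kymograph_spec"))
  a <- spec$pixel_size_um
  extent <- spec$n_pixels * a
  if (any(traj$x_um < 0) || any(traj$x_um >= extent))
    stop("trajectory leaves the imaged extent [0, n_pixels * pixel_size)")
  with_seed(spec$seed, {
    nl <- nrow(traj)
    np <- spec$n_pixels
    counts <- matrix(0L, nrow = np, ncol = nl)
    for (j in seq_len(nl)) {
      nph <- stats::rpois(1, spec$photons_mean)
      if (nph > 0) {
        px <- floor((traj$x_um[j] +
                     stats::rnorm(nph, 0, spec$psf_sigma_um)) / a)
        px <- px[px >= 0 & px < np]
        if (length(px)) {
          tb <- tabulate(px + 1L, nbins = np)
          counts[, j] <- counts[, j] + tb
        }
      }
      if (spec$background_mean > 0)
        counts[, j] <- counts[, j] +
          stats::rpois(np, spec$background_mean / 5)
    }
    kymograph(counts, a, frame_interval(traj))
  })
}

#' Simulate single-molecule binding-event streams
#'
#' First-binding times are exponential with pseudo-first-order rate
#' `k_on_per_bp * dna_length_bp * concentration` (the on-rate scales
#' linearly with DNA length: more basepairs, more binding sites); dwell
#' times are exponential with mean `mean_lifetime`. Both are
#' right-censored at the end of the observation window.
#'
#' @param k_on_per_bp per-basepair association rate, 1/(M s bp).
#' @param dna_length_bp DNA length, bp.
#' @param concentration protein concentration, M.
#' @param mean_lifetime mean bound-state lifetime, s.
#' @param n_molecules number of DNA molecules observed.
#' @param observation_window observation time, s.
#' @param seed optional RNG seed.
#' @return object of class `binding_events`: data.frame with columns
#'   `molecule_id`, `t_first_s`, `t_first_censored`, `dwell_s`,
#'   `dwell_censored`; concentration and DNA length kept as attributes.
#' @export
simulate_binding_events <- function(k_on_per_bp, dna_length_bp,
                                    concentration, mean_lifetime,
                                    n_molecules,
                                    observation_window = Inf,
                                    seed = NULL) {
  stop_if_not_scalar(k_on_per_bp, "k_on_per_bp", positive = TRUE)
  stop_if_not_scalar(dna_length_bp, "dna_length_bp", positive = TRUE)
  stop_if_not_scalar(concentration, "concentration", positive = TRUE)
  stop_if_not_scalar(mean_lifetime, "mean_lifetime", positive = TRUE)
  stop_if_not_scalar(n_molecules, "n_molecules", positive = TRUE)
  with_seed(seed, {
    n <- as.integer(n_molecules)
    rate <- k_on_per_bp * dna_length_bp * concentration
    t_first <- stats::rexp(n, rate)
    dwell <- stats::rexp(n, 1 / mean_lifetime)
    tf_cens <- t_first > observation_window
    t_first_obs <- pmin(t_first, observation_window)
    dw_cens <- tf_cens | (t_first + dwell > observation_window)
    dwell_obs <- ifelse(tf_cens, NA_real_,
                        pmin(dwell, observation_window - t_first))
    out <- data.frame(molecule_id = seq_len(n),
                      t_first_s = t_first_obs,
                      t_first_censored = tf_cens,
                      dwell_s = dwell_obs,
                      dwell_censored = dw_cens)
    structure(out, class = c("binding_events", "data.frame"),
              concentration_M = concentration,
              dna_length_bp = dna_length_bp,
              seed = seed)
  })
}

#' Synthetic force-extension configuration
#'
#' States the geometry of a nucleosome-array pulling experiment: a
#' worm-like-chain DNA baseline whose available contour length grows as
#' nucleosomes unwrap. Each wrapped nucleosome sequesters enough contour
#' length that the tether is shorter by `lengthening_at_5pN_nm` per
#' nucleosome when held at 5 pN; the inner-turn release at the unwrap
#' force (drawn uniformly from `unwrap_force_range`) produces an abrupt
#' extension step of `step_size_nm`, with the remaining sequestered
#' contour released gradually between 5 pN and the low end of the unwrap
#' window (outer-turn peeling).
#'
#' @param n_nucleosomes number of nucleosomes on the array.
#' @param step_size_nm abrupt extension gain per unwrapping event, nm.
#' @param unwrap_force_range forces between which inner turns pop, pN.
#' @param naked_contour_length_um contour length of the naked DNA, um
#'   (16.5 for lambda).
#' @param persistence_length_nm worm-like-chain persistence length, nm.
#' @param lengthening_at_5pN_nm tether lengthening at 5 pN per unwrapped
#'   nucleosome, nm.
#' @param noise_sd_nm additive Gaussian distance noise, nm.
#' @param force_range pN range of the ramp.
#' @param force_step pN per sample of the ramp.
#' @param ramp `"updown"` (default; ramp to max force and back, so the
#'   5 pN length can be read before and after unwrapping) or `"up"`.
#' @param kT thermal energy, pN nm.
#' @param seed optional RNG seed.
#' @return object of class `fd_config`.
#' @export
fd_config <- function(n_nucleosomes, step_size_nm = 25,
                      unwrap_force_range = c(15, 30),
                      naked_contour_length_um = 16.5,
                      persistence_length_nm = 50,
                      lengthening_at_5pN_nm = 34.6,
                      noise_sd_nm = 2,
                      force_range = c(0.5, 35), force_step = 0.001,
                      ramp = c("updown", "up"), kT = 4.1143,
                      seed = NULL) {
  stop_if_not_scalar(n_nucleosomes, "n_nucleosomes", nonnegative = TRUE)
  stop_if_not_scalar(step_size_nm, "step_size_nm", positive = TRUE)
  stopifnot(length(unwrap_force_range) == 2,
            all(unwrap_force_range > 0),
            unwrap_force_range[1] < unwrap_force_range[2])
  stop_if_not_scalar(naked_contour_length_um, "naked_contour_length_um",
                     positive = TRUE)
  stop_if_not_scalar(persistence_length_nm, "persistence_length_nm",
                     positive = TRUE)
  stop_if_not_scalar(lengthening_at_5pN_nm, "lengthening_at_5pN_nm",
                     positive = TRUE)
  stop_if_not_scalar(noise_sd_nm, "noise_sd_nm", nonnegative = TRUE)
  ramp <- match.arg(ramp)
  structure(list(n_nucleosomes = as.integer(n_nucleosomes),
                 step_size_nm = step_size_nm,
                 unwrap_force_range = unwrap_force_range,
                 naked_contour_length_um = naked_contour_length_um,
                 persistence_length_nm = persistence_length_nm,
                 lengthening_at_5pN_nm = lengthening_at_5pN_nm,
                 noise_sd_nm = noise_sd_nm,
                 force_range = force_range, force_step = force_step,
                 ramp = ramp, kT = kT, seed = seed),
            class = "fd_config")
}

# Marko-Siggia worm-like-chain relative extension x/Lc at force F (pN),
# solved numerically; vectorized over F. Long inputs are interpolated
# from a 1000-point spline of the (smooth, monotone) inverse relation.
wlc_extension_fraction <- function(force_pN, persistence_length_nm = 50,
                                   kT = 4.1143) {
  fac <- kT / persistence_length_nm  # pN
  solve1 <- function(f) {
    if (f <= 0) return(0)
    g <- function(z) fac * (1 / (4 * (1 - z)^2) - 0.25 + z) - f
    stats::uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  }
  if (length(force_pN) <= 1000)
    return(vapply(force_pN, solve1, numeric(1)))
  grid <- seq(min(force_pN), max(force_pN), length.out = 1000)
  sp <- stats::splinefun(grid, vapply(grid, solve1, numeric(1)),
                         method = "hyman")
  sp(force_pN)
}

#' Simulate a force-extension curve of a nucleosome array
#'
#' See [fd_config()] for the generative model. The returned curve
#' carries the ground-truth unwrap forces and per-event distance steps
#' as attribute `"truth"`.
#'
#' @param cfg an [fd_config()].
#' @return object of class `force_extension`: data.frame with columns
#'   `force_pN`, `distance_um`, `segment` ("up"/"down").
#' @export
simulate_force_extension <- function(cfg) {
  stopifnot(inherits(cfg, "fd_config"))
  with_seed(cfg$seed, {
    n_nuc <- cfg$n_nucleosomes
    f_up <- seq(cfg$force_range[1], cfg$force_range[2],
                by = cfg$force_step)
    phi_up <- wlc_extension_fraction(f_up, cfg$persistence_length_nm,
                                     cfg$kT)
    phi5 <- wlc_extension_fraction(5, cfg$persistence_length_nm, cfg$kT)
    grad_lo <- 5
    grad_hi <- cfg$unwrap_force_range[1]

    unwrap_f <- if (n_nuc > 0)
      sort(stats::runif(n_nuc, cfg$unwrap_force_range[1],
                        cfg$unwrap_force_range[2])) else numeric(0)
    # contour sequestered per nucleosome (nm): total fixes the 5 pN
    # compaction relation; the abrupt part fixes the step size
    c_tot <- cfg$lengthening_at_5pN_nm / phi5
    phi_at_unwrap <- wlc_extension_fraction(unwrap_f,
                                            cfg$persistence_length_nm,
                                            cfg$kT)
    c_abrupt <- cfg$step_size_nm / phi_at_unwrap
    c_grad <- pmax(c_tot - c_abrupt, 0)

    # contour length (um) available at force F on the up ramp
    contour_up <- vapply(seq_along(f_up), function(i) {
      f <- f_up[i]
      released <- 0
      if (n_nuc > 0) {
        frac <- min(max((f - grad_lo) / (grad_hi - grad_lo), 0), 1)
        popped <- unwrap_f <= f
        released <- sum(ifelse(popped, c_abrupt + c_grad,
                               frac * c_grad))
      }
      cfg$naked_contour_length_um - (n_nuc * c_tot - released) * 1e-3
    }, numeric(1))
    d_up <- contour_up * phi_up

    df <- data.frame(force_pN = f_up, distance_um = d_up,
                     segment = "up")
    if (cfg$ramp == "updown") {
      f_dn <- rev(f_up)
      d_dn <- cfg$naked_contour_length_um * rev(phi_up)
      df <- rbind(df, data.frame(force_pN = f_dn, distance_um = d_dn,
                                 segment = "down"))
    }
    if (cfg$noise_sd_nm > 0)
      df$distance_um <- df$distance_um +
        stats::rnorm(nrow(df), 0, cfg$noise_sd_nm * 1e-3)
    structure(df, class = c("force_extension", "data.frame"),
              truth = list(unwrap_forces_pN = unwrap_f,
                           step_sizes_nm = cfg$step_size_nm,
                           n_nucleosomes = n_nuc),
              config = cfg)
  })
}
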