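# Shared fixtures, all generated in code at test time.

# brute-force MSD oracle: literal double loop over displacement pairs
msd_oracle <- function(x, dt) {
  N <- length(x)
  msd <- numeric(N - 1)
  for (n in seq_len(N - 1)) {
    acc <- 0
    for (i in seq_len(N - n)) acc <- acc + (x[i + n] - x[i])^2
    msd[n] <- acc / (N - n)
  }
  data.frame(lag = seq_len(N - 1), lag_time_s = seq_len(N - 1) * dt,
             msd_um2 = msd)
}

# ensemble of noisy Brownian trajectories at the conditions used for
# remodeler-scale data (600 frames at 50 ms, 82 nm localization noise)
make_ensemble <- function(n_traces, D_true, seed0,
                          n_frames = 600, dt = 0.05,
                          noise = 0.082) {
  lapply(seq_len(n_traces), function(i) {
    gt <- simulate_trajectory(sim_config(D_true, dt, n_frames, x0 = 3,
                                         seed = seed0 + i))
    add_localization_noise(gt, noise, seed = seed0 + 10000 + i)
  })
}

# exact synthetic MSD curve msd = f(t) on a 50 ms lag grid
synthetic_msd <- function(f, n_lags = 100, dt = 0.05) {
  t <- seq_len(n_lags) * dt
  structure(data.frame(lag = seq_len(n_lags), lag_time_s = t,
                       msd_um2 = f(t), n_pairs = n_lags + 1 - seq_len(n_lags)),
            class = c("msd_curve", "data.frame"),
            frame_interval = dt, id = "synthetic")
}
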