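# Sub-pixel tracking and the localization-precision formula.

test_that("localization precision has the right limits and monotonicity", {
  # background-free, small pixels: sigma -> s / sqrt(N)
  expect_equal(localization_precision(294, 12.9, 1e-6, 0),
               294 / sqrt(12.9), tolerance = 1e-6)
  # published operating point (first two terms dominate): ~82 nm
  expect_equal(localization_precision(294, 12.9, 100, 0), 82,
               tolerance = 0.005)
  # quadrupling photons halves sigma at b = 0
  expect_equal(localization_precision(294, 4 * 12.9, 100, 0) * 2,
               localization_precision(294, 12.9, 100, 0), tolerance = 1e-9)
  # strictly decreasing in N, increasing in b
  Ns <- c(5, 10, 20, 40, 80)
  sig <- vapply(Ns, function(N)
    localization_precision(294, N, 100, 0.8), numeric(1))
  expect_true(all(diff(sig) < 0))
  bs <- c(0, 0.4, 0.8, 1.6)
  sig_b <- vapply(bs, function(b)
    localization_precision(294, 12.9, 100, b), numeric(1))
  expect_true(all(diff(sig_b) > 0))
  expect_error(localization_precision(-1, 10, 100))
})

test_that("noiseless symmetric spot tracks to its exact centre", {
  # delta-like spot: put a symmetric discretized Gaussian at pixel 20
  np <- 40
  centers <- (seq_len(np) - 0.5) * 0.1
  x0 <- (20 + 0.5) * 0.1  # centre of 0-based pixel 20
  prof <- round(1000 * (pnorm(centers + 0.05, x0, 0.294) -
                        pnorm(centers - 0.05, x0, 0.294)))
  ky <- kymograph(matrix(rep(prof, 50), nrow = np), 0.1, 0.05)
  tk <- track_kymograph(ky)
  expect_equal(unique(round(tk$x_um, 6)), x0, tolerance = 1e-4)
})

test_that("tracking is translation-equivariant", {
  tr <- trajectory(rep(2.03, 60), 0.05)
  ky <- render_kymograph(tr, kymograph_spec(photons_mean = 200,
                                            background_mean = 0, seed = 13))
  shift <- 7L
  ky2 <- kymograph(rbind(matrix(0L, shift, ncol(ky$counts)),
                         ky$counts[seq_len(64 - shift), ]),
                   ky$pixel_size_um, ky$line_time_s)
  t1 <- track_kymograph(ky)
  t2 <- track_kymograph(ky2)
  expect_equal(t2$x_um, t1$x_um + shift * 0.1, tolerance = 1e-6)
})

test_that("closed loop: static particle recovered at photon-budget precision", {
  tr <- trajectory(rep(2.03, 600), 0.05, id = "static")
  ky <- render_kymograph(tr, kymograph_spec(seed = 7))
  tk <- track_kymograph(ky)
  ok <- !tk$interpolated
  # mean position unbiased to < 0.1 pixel
  expect_lt(abs(mean(tk$x_um[ok]) - 2.03), 0.01)
  # empirical precision within a factor of 2 of the b->0 formula value
  expect_lt(sd(tk$x_um[ok]), 2 * 0.082)
  expect_gt(sd(tk$x_um[ok]), 0.082 / 2)
})

test_that("closed loop: moving particle RMS error within the photon budget", {
  gt <- simulate_trajectory(sim_config(0.024, 0.05, 400, x0 = 3, seed = 11))
  ky <- render_kymograph(gt, kymograph_spec(n_pixels = 64, seed = 12))
  tk <- track_kymograph(ky)
  idx <- match(round(tk$time_s, 9), round(gt$trajectory$time_s, 9))
  ok <- !tk$interpolated & !is.na(idx)
  rms <- sqrt(mean((tk$x_um[ok] - gt$trajectory$x_um[idx[ok]])^2))
  # bounded by the full three-term formula at the rendered budget
  pred_full <- localization_precision(294, 12.9, 100, 0.8) / 1000
  expect_lt(rms, pred_full)
  expect_gt(rms, 0.082 / 2)
})

test_that("missing lines are interpolated and long gaps split the track", {
  tr <- trajectory(rep(1.55, 80), 0.05)
  ky <- render_kymograph(tr, kymograph_spec(photons_mean = 100,
                                            background_mean = 0,
                                            n_pixels = 32, seed = 14))
  # knock out 2 lines (bridged) and 6 lines (split)
  ky$counts[, 11:12] <- 0L
  tk <- track_kymograph(ky, min_photons = 5)
  expect_true(all(tk$interpolated[11:12]))
  expect_equal(nrow(tk), 80)
  ky$counts[, 41:46] <- 0L
  expect_message(tk2 <- track_kymograph(ky, min_photons = 5), "split")
  expect_equal(nrow(tk2), 40)  # longest segment (lines before the gap)
  expect_length(attr(tk2, "segments"), 2)
})
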