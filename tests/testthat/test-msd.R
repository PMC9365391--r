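# MSD computation, diffusion-coefficient fitting with refinement,
# anomalous exponents, plateaus and ensemble statistics.

test_that("compute_msd matches hand-derived values and the brute-force oracle", {
  # hand evaluation: X = 0,1,2,3 -> msd = 1, 4, 9
  m <- compute_msd(trajectory(c(0, 1, 2, 3), 1))
  expect_equal(m$msd_um2, c(1, 4, 9))
  expect_equal(m$n_pairs, c(3, 2, 1))
  # constant trajectory -> all zeros
  expect_true(all(compute_msd(trajectory(rep(2, 20), 0.05))$msd_um2 == 0))
  # random trajectories against the double-loop oracle
  set.seed(17)
  for (rep in 1:25) {
    N <- sample(3:50, 1)
    x <- cumsum(rnorm(N))
    expect_equal(compute_msd(trajectory(x, 0.05))$msd_um2,
                 msd_oracle(x, 0.05)$msd_um2, tolerance = 1e-12)
  }
})

test_that("D estimate is exact on a clean line and invariant to offset/flip", {
  m <- synthetic_msd(function(t) 2 * 0.01 * t)
  est <- fit_diffusion_coefficient(m)
  expect_equal(est$D_um2_s, 0.01, tolerance = 1e-10)
  expect_equal(est$r2, 1, tolerance = 1e-10)
  expect_false(est$rejected)
  # offset and sign flip of the trajectory leave D unchanged
  gt <- simulate_trajectory(sim_config(0.02, 0.05, 300, seed = 41))
  x <- gt$x_um
  d0 <- fit_diffusion_coefficient(compute_msd(trajectory(x, 0.05)))$D_um2_s
  d1 <- fit_diffusion_coefficient(compute_msd(trajectory(x + 5, 0.05)))$D_um2_s
  d2 <- fit_diffusion_coefficient(compute_msd(trajectory(-x, 0.05)))$D_um2_s
  expect_equal(d1, d0, tolerance = 1e-12)
  expect_equal(d2, d0, tolerance = 1e-12)
})

test_that("negative slopes clamp to zero and outliers are flagged", {
  dec <- synthetic_msd(function(t) 0.5 - 0.1 * t, n_lags = 4)
  est <- fit_diffusion_coefficient(dec)
  expect_equal(est$D_um2_s, 0)
  expect_equal(est$method, "clamped-zero")
  fast <- synthetic_msd(function(t) 2 * 0.5 * t)
  est2 <- fit_diffusion_coefficient(fast)  # D = 0.5 > 0.14 cutoff
  expect_true(est2$rejected)
  expect_equal(est2$reason, "outlier-cutoff")
  est3 <- fit_diffusion_coefficient(fast, refinement_rules(d_max = 5))
  expect_false(est3$rejected)
  # degenerate all-zero curve is D = 0, not an error
  z <- synthetic_msd(function(t) 0 * t)
  expect_equal(fit_diffusion_coefficient(z)$D_um2_s, 0)
})

test_that("ensemble median recovers simulated D across magnitudes", {
  trajs <- make_ensemble(60, 0.024, seed0 = 9000)
  ests <- lapply(trajs, function(tr)
    fit_diffusion_coefficient(compute_msd(tr)))
  ens <- ensemble_stats(ests, n_boot = 1000, seed = 1)
  expect_equal(ens$median_D, 0.024, tolerance = 0.1)
  expect_lt(ens$n_pre - ens$n_post, 0.05 * ens$n_pre)  # few rejections
  # faster particle, small-domain rules
  fast <- make_ensemble(40, 0.5, seed0 = 9500, noise = 0.03)
  ef <- lapply(fast, function(tr)
    fit_diffusion_coefficient(compute_msd(tr), refinement_rules(d_max = 5)))
  expect_equal(median(vapply(ef, `[[`, numeric(1), "D_um2_s")), 0.5,
               tolerance = 0.15)
})

test_that("anomalous exponent hits the analytic limits", {
  expect_equal(fit_anomalous(synthetic_msd(function(t) 0.05 * t))$alpha,
               1, tolerance = 1e-9)
  expect_equal(fit_anomalous(synthetic_msd(function(t) 0.05 * t^2))$alpha,
               2, tolerance = 1e-9)
  # confinement pushes alpha well below 1
  gt <- simulate_trajectory(sim_config(0.024, 0.05, 4000, x0 = 0.2,
                                       boundaries = c(0, 0.35), seed = 43))
  af <- fit_anomalous(compute_msd(gt$trajectory), window_s = 2)
  expect_lt(af$alpha, 0.5)
  expect_error(fit_anomalous(synthetic_msd(function(t) 0 * t)))
})

test_that("plateau fit recovers the limit and flags non-saturating curves", {
  m <- synthetic_msd(function(t) 0.054 * (1 - exp(-t / 0.4)), n_lags = 200)
  pf <- fit_plateau(m)
  expect_true(pf$saturating)
  expect_equal(pf$msd_limit_um2, 0.054, tolerance = 1e-6)
  expect_equal(pf$confinement_length_um, 0.2324, tolerance = 0.001)
  expect_equal(pf$interval_length_um, sqrt(6 * 0.054), tolerance = 1e-6)
  lin <- fit_plateau(synthetic_msd(function(t) 0.01 * t))
  expect_false(lin$saturating)
})

test_that("ensemble statistics: fractions, uncertainty and bootstrap CI", {
  zeros <- lapply(1:20, function(i) kymodiff:::new_diffusion_estimate(
    0, 0, 0, 5, NA_real_, NA_real_, "clamped-zero", refinement_rules()))
  ens0 <- ensemble_stats(zeros, n_boot = 200, seed = 2)
  expect_equal(ens0$mobile_fraction, 0)
  expect_equal(ens0$median_D, 0)
  # uncertainty definition: SEM * sqrt(pi/2)
  tab <- data.frame(D_um2_s = c(0.001, 0.02, 0.03, 0.05), rejected = FALSE)
  ens <- ensemble_stats(tab, n_boot = 200, seed = 3)
  expect_equal(ens$median_uncertainty,
               sd(tab$D_um2_s) / sqrt(4) * sqrt(pi / 2))
  expect_equal(ens$mobile_fraction, 0.75)
  expect_error(ensemble_stats(data.frame(D_um2_s = 1, rejected = TRUE)))
})

test_that("bootstrap CI on the mobile fraction has near-nominal coverage", {
  # known Bernoulli(0.7) mobile share, 60 traces, 200 replications
  set.seed(71)
  hits <- 0; n_rep <- 200
  for (r in 1:n_rep) {
    D <- ifelse(runif(50) < 0.7, 0.02, 0.001)
    tab <- data.frame(D_um2_s = D, rejected = FALSE)
    ci <- ensemble_stats(tab, n_boot = 300)$mobile_fraction_ci
    if (ci[1] <= 0.7 && 0.7 <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.85)  # percentile bootstrap, modest n
})

test_that("mean_msd averages per lag and refuses mixed frame rates", {
  c1 <- compute_msd(trajectory(c(0, 1, 2, 3), 0.05))
  c2 <- compute_msd(trajectory(c(0, 0, 0, 0, 0), 0.05))
  m <- mean_msd(list(c1, c2))
  expect_equal(m$msd_um2[1:3], c1$msd_um2 / 2)
  expect_equal(m$n_pairs, c(2, 2, 2, 1))
  c3 <- compute_msd(trajectory(c(0, 1), 0.02))
  expect_error(mean_msd(list(c1, c3)))
})
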