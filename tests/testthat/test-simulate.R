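# The synthetic-data generator is itself first-class code: its
# distributions are what every closed-loop recovery relies on.

test_that("increments are Gaussian with variance 2*D*dt", {
  gt <- simulate_trajectory(sim_config(0.024, 0.05, 10001, seed = 3))
  inc <- diff(gt$x_um)
  expect_equal(var(inc), 2 * 0.024 * 0.05, tolerance = 0.05)
  ks <- ks.test(inc, "pnorm", 0, sqrt(2 * 0.024 * 0.05))
  expect_gt(ks$p.value, 0.01)
  # D = 0 freezes the particle
  gt0 <- simulate_trajectory(sim_config(0, 0.05, 100, x0 = 1.2, seed = 1))
  expect_true(all(gt0$x_um == 1.2))
})

test_that("reflecting boundaries confine and equilibrate to uniform", {
  gt <- simulate_trajectory(sim_config(0.024, 0.05, 20000, x0 = 0.1,
                                       boundaries = c(0, 0.35), seed = 4))
  expect_true(all(gt$x_um >= 0 & gt$x_um <= 0.35))
  # uniform stationary law: decimated positions (lag ~ mixing time)
  sub <- gt$x_um[seq(1000, 20000, by = 40)]
  expect_gt(ks.test(sub, "punif", 0, 0.35)$p.value, 0.01)
  # long-lag MSD plateau at L^2/6
  m <- compute_msd(gt$trajectory)
  plateau <- mean(m$msd_um2[m$lag > 100 & m$lag < 2000])
  expect_equal(plateau, 0.35^2 / 6, tolerance = 0.1)
})

test_that("fixed seed gives bit-identical output and bad configs are rejected", {
  a <- simulate_trajectory(sim_config(0.01, 0.05, 200, seed = 9))
  b <- simulate_trajectory(sim_config(0.01, 0.05, 200, seed = 9))
  expect_identical(a$x_um, b$x_um)
  expect_error(sim_config(-1, 0.05, 10))
  expect_error(sim_config(0.01, 0.05, 10, boundaries = c(1, 0.5)))
  expect_error(sim_config(0.01, 0.05, 10, roadblocks =
    list(list(position = 1, p_reflect = 0.5, p_stick = 0.2, p_cross = 0.1))))
  expect_error(sim_config(0.01, 0.05, 10, bleach_rate = NaN))
})

test_that("lifetime truncation follows the pooled exponential rate", {
  n_alive <- vapply(1:300, function(i) {
    gt <- simulate_trajectory(sim_config(0.01, 0.05, 2000,
                                         bleach_rate = 0.15,
                                         unbind_rate = 0.05, seed = 100 + i))
    sum(gt$alive)
  }, numeric(1))
  # mean observable lifetime = 1 / (bleach + unbind) = 5 s = 100 frames
  expect_equal(mean(n_alive) * 0.05, 5, tolerance = 0.15)
})

test_that("roadblock episodes draw one outcome per entry and honor it", {
  mk <- function(p, seed) simulate_trajectory(sim_config(
    0.05, 0.05, 2000, x0 = 0.5, boundaries = c(0, 2),
    roadblocks = list(c(list(position = 1), p)), seed = seed))
  refl <- mk(list(p_reflect = 1, p_stick = 0, p_cross = 0), 21)
  expect_true(all(refl$x_um <= 1 + 1e-12))
  expect_true(all(refl$events$outcome == "reflect"))
  expect_gt(nrow(refl$events), 2)
  crs <- mk(list(p_reflect = 0, p_stick = 0, p_cross = 1), 22)
  expect_gt(max(crs$x_um), 1.1)  # does get past the roadblock
  stk <- mk(list(p_reflect = 0, p_stick = 1, p_cross = 0), 23)
  i_stick <- which(stk$x_um == 1)[1]
  expect_true(all(stk$x_um[i_stick:length(stk$x_um)] == 1))
})

test_that("binding-event streams have the stated exponential structure", {
  be <- simulate_binding_events(1e5, 150, 5e-9, 12, 2000, Inf, seed = 5)
  rate <- 1e5 * 150 * 5e-9
  expect_equal(mean(be$t_first_s), 1 / rate, tolerance = 0.05)
  expect_equal(mean(be$dwell_s), 12, tolerance = 0.06)
  # doubling DNA length halves the mean first-binding time
  be2 <- simulate_binding_events(1e5, 300, 5e-9, 12, 2000, Inf, seed = 5)
  expect_equal(mean(be2$t_first_s) / mean(be$t_first_s), 0.5,
               tolerance = 0.08)
  # censoring recorded
  bec <- simulate_binding_events(1e5, 150, 5e-9, 12, 500, 5, seed = 6)
  expect_true(any(bec$t_first_censored))
  expect_true(all(bec$t_first_s <= 5))
})

test_that("kymograph renderer gives Poisson counts around the PSF profile", {
  tr <- trajectory(rep(3.25, 3000), 0.05)  # centre of pixel 32
  ky <- render_kymograph(tr, kymograph_spec(photons_mean = 40,
                                            background_mean = 0, seed = 8))
  prof <- rowMeans(ky$counts)
  centers <- (seq_len(64) - 1 + 0.5) * 0.1
  expected <- 40 * (pnorm(centers + 0.05, 3.25, 0.294) -
                    pnorm(centers - 0.05, 3.25, 0.294))
  expect_gt(cor(prof, expected), 0.999)
  expect_equal(sum(prof), 40, tolerance = 0.05)
  # degenerate: no photons at all
  ky0 <- render_kymograph(trajectory(rep(1, 10), 0.05),
                          kymograph_spec(photons_mean = 0,
                                         background_mean = 0, n_pixels = 32))
  expect_true(all(ky0$counts == 0))
  expect_error(render_kymograph(trajectory(c(10, 10), 0.05),
                                kymograph_spec(n_pixels = 32)))
})

test_that("force-extension curves have the stated step geometry", {
  cfg <- fd_config(40, noise_sd_nm = 0.5, seed = 31)
  cv <- simulate_force_extension(cfg)
  tr <- attr(cv, "truth")
  expect_equal(tr$n_nucleosomes, 40)
  expect_true(all(tr$unwrap_forces_pN >= 15 & tr$unwrap_forces_pN <= 30))
  # 5 pN compaction relation: exactly 34.6 nm per nucleosome
  before <- length_at_force(cv, 5, "up")
  after <- length_at_force(cv, 5, "down")
  expect_equal((after - before) * 1000, 40 * 34.6, tolerance = 0.01)
  # zero-nucleosome curve is smooth
  cv0 <- simulate_force_extension(fd_config(0, noise_sd_nm = 0.5, seed = 32))
  expect_equal(detect_unwrapping_steps(cv0)$n_steps, 0L)
  # at 5 pN a naked tether sits in the >90% extension regime (the
  # plain Marko-Siggia chain at P = 50 nm gives ~0.936; the empirical
  # 0.92 for lambda DNA includes enthalpic corrections not modelled)
  frac <- length_at_force(cv0, 5, "up") / 16.5
  expect_gt(frac, 0.9); expect_lt(frac, 0.95)
})
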