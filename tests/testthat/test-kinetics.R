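# On-rates from first-arrival times, lifetimes from dwell survival,
# photobleaching correction.

test_that("k_bind arithmetic and unit invariances", {
  ev <- data.frame(t_first_s = rep(10, 20), t_first_censored = FALSE)
  res <- estimate_kbind(ev, concentration_M = 5e-9, dna_length_bp = 150)
  expect_equal(res$k_bind, 1 / (10 * 5e-9))  # 2e7 /M/s
  expect_equal(res$k_bind_per_bp, res$k_bind / 150)
  # doubling concentration halves t_first but leaves k_bind unchanged
  be1 <- simulate_binding_events(2e5, 150, 5e-9, 12, 400, Inf, seed = 61)
  be2 <- simulate_binding_events(2e5, 150, 1e-8, 12, 400, Inf, seed = 61)
  k1 <- estimate_kbind(be1); k2 <- estimate_kbind(be2)
  expect_equal(mean(be2$t_first_s) / mean(be1$t_first_s), 0.5,
               tolerance = 1e-9)  # same uniforms, scaled rates
  expect_equal(k1$k_bind, k2$k_bind, tolerance = 1e-9)
  # time-unit rescaling: rates scale inversely
  ev_min <- data.frame(t_first_s = rep(10, 20) / 60,
                       t_first_censored = FALSE)
  res_min <- estimate_kbind(ev_min, 5e-9, 150)
  expect_equal(res_min$rate_s, res$rate_s * 60)
  expect_error(estimate_kbind(data.frame(t_first_s = rep(1, 5),
                                         t_first_censored = FALSE),
                              5e-9, 150))
})

test_that("k_bind recovery and linearity in DNA length", {
  k_true <- 3.6e7 / 150  # per-bp rate giving 3.6e7 at 150 bp
  lens <- c(20, 60, 100, 150)
  ks <- vapply(seq_along(lens), function(i) {
    be <- simulate_binding_events(k_true, lens[i], 5e-9, 12, 500, Inf,
                                  seed = 70 + i)
    estimate_kbind(be)$k_bind
  }, numeric(1))
  expect_equal(ks[4], 3.6e7, tolerance = 0.1)
  # linear through the origin: per-bp normalization is flat
  expect_lt(max(abs(ks / lens - k_true * 1)) / (k_true), 0.15)
  f <- kymodiff:::linfit(lens, ks)
  expect_gt(f$r2, 0.97)
})

test_that("survival fit recovers exponential lifetimes, censoring-aware", {
  set.seed(81)
  dw <- rexp(300, 1 / 12)
  sv <- fit_survival(dw)
  expect_equal(sv$tau_s, 12, tolerance = 0.1)
  expect_equal(sv$half_life_s, sv$tau_s * log(2))
  expect_false(sv$flagged)
  # right-censoring at 15 s still recovers tau via Kaplan-Meier
  cens <- dw > 15
  svc <- fit_survival(pmin(dw, 15), cens)
  expect_equal(svc$tau_s, 12, tolerance = 0.15)
  # all censored -> unbounded, flagged
  sv_all <- fit_survival(rep(5, 20), rep(TRUE, 20))
  expect_true(is.infinite(sv_all$tau_s))
  expect_true(sv_all$flagged)
  # strong two-component mixture is flagged as non-exponential
  mix <- c(rexp(150, 1 / 0.5), rexp(150, 1 / 40))
  expect_true(fit_survival(mix)$flagged)
})

test_that("photobleach correction extrapolates to zero power", {
  # line through two points: (1, 0.02), (2, 0.03) -> intercept 0.01
  pb <- photobleach_correction(c(1, 2), c(0.02, 0.03))
  expect_equal(pb$intrinsic_off_rate, 0.01, tolerance = 1e-12)
  expect_equal(pb$intrinsic_lifetime_s, 100)
  # constant apparent rate -> intrinsic equals it
  pb2 <- photobleach_correction(c(1, 2, 3), rep(0.05, 3))
  expect_equal(pb2$intrinsic_off_rate, 0.05)
  # synthetic bleach ~ power on top of a 3-minute intrinsic lifetime
  set.seed(82)
  powers <- c(0.5, 1, 2, 4)
  apparent <- vapply(powers, function(p) {
    dw <- rexp(400, rate = 1 / 180 + 0.01 * p)
    1 / mean(dw)
  }, numeric(1))
  pb3 <- photobleach_correction(powers, apparent)
  expect_equal(pb3$intrinsic_lifetime_s / 60, 3, tolerance = 0.25)
  expect_warning(photobleach_correction(c(1, 2), c(0.01, 0.05)),
                 "clamping")
})
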