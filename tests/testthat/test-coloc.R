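# Roadblock encounter classification and trace extension.

test_that("extend_after_bleach appends the mean observed position", {
  rb <- trajectory(rep(3.00, 100), 0.05)
  ext <- extend_after_bleach(rb, 150)
  expect_equal(nrow(ext), 150)
  expect_true(all(ext$x_um == 3.00))
  expect_true(all(ext$interpolated[101:150]))
  noisy <- trajectory(3.02 + rnorm(100, 0, 0.01), 0.05)
  ext2 <- extend_after_bleach(noisy, 120)
  expect_equal(unique(ext2$x_um[101:120]), mean(noisy$x_um))
  # no bleach: unchanged
  expect_identical(nrow(extend_after_bleach(rb, 100)), 100L)
  expect_error(extend_after_bleach(trajectory(c(1, 1, 1), 0.05), 10))
})

test_that("pure reflect / pure cross simulators classify 100% accordingly", {
  mk <- function(p, seed) simulate_trajectory(sim_config(
    0.05, 0.05, 1500, x0 = 0.6, boundaries = c(0, 2),
    roadblocks = list(c(list(position = 1.2), p)), seed = seed))
  refl <- mk(list(p_reflect = 1, p_stick = 0, p_cross = 0), 91)
  er <- classify_encounters(refl$trajectory, 1.2, radius = 0.082,
                            stuck_min_duration = 5,
                            censored_at_end = "exclude")
  expect_gt(nrow(er$events), 3)
  expect_true(all(er$events$classification == "reflected"))
  crs <- mk(list(p_reflect = 0, p_stick = 0, p_cross = 1), 92)
  ec <- classify_encounters(crs$trajectory, 1.2, radius = 0.082,
                            stuck_min_duration = 5,
                            censored_at_end = "exclude")
  expect_gt(nrow(ec$events), 3)
  expect_true(all(ec$events$classification == "crossover"))
})

test_that("stuck particles are classified stuck through the trace end", {
  gt <- simulate_trajectory(sim_config(
    0.05, 0.05, 800, x0 = 0.6, boundaries = c(0, 2),
    roadblocks = list(list(position = 1.2, p_reflect = 0, p_stick = 1,
                           p_cross = 0)), seed = 93))
  es <- classify_encounters(gt$trajectory, 1.2, radius = 0.082)
  expect_equal(nrow(es$events), 1)
  expect_equal(es$events$classification, "stuck")
})

test_that("classification is invariant to reflecting the spatial axis", {
  gt <- simulate_trajectory(sim_config(
    0.024, 0.05, 600, x0 = 0.8, boundaries = c(0, 3),
    roadblocks = list(list(position = 1.5, p_reflect = 0.6, p_stick = 0.3,
                           p_cross = 0.1)), seed = 94))
  a <- classify_encounters(gt$trajectory, 1.5, radius = 0.082)
  flipped <- trajectory(3 - gt$trajectory$x_um, 0.05)
  b <- classify_encounters(flipped, 3 - 1.5, radius = 0.082)
  expect_equal(a$events$classification, b$events$classification)
  expect_equal(a$fractions, b$fractions)
})

test_that("mobile roadblocks and degenerate radii are rejected/empty", {
  wander <- trajectory(cumsum(rnorm(100, 0, 0.2)), 0.05)
  still <- trajectory(rep(1, 100), 0.05)
  expect_error(classify_encounters(still, wander, radius = 0.1),
               "mobile")
  far <- classify_encounters(trajectory(rep(5, 50), 0.05), 1.0,
                             radius = 0.01)
  expect_equal(nrow(far$events), 0)
  expect_true(all(is.na(far$fractions)))
})

test_that("fractions sum to 1 over events", {
  gt <- simulate_trajectory(sim_config(
    0.024, 0.05, 600, x0 = 1, boundaries = c(0, 3),
    roadblocks = list(list(position = 1.5, p_reflect = 0.67,
                           p_stick = 0.30, p_cross = 0.03)), seed = 95))
  es <- classify_encounters(gt$trajectory, 1.5, radius = 0.082)
  if (nrow(es$events)) expect_equal(sum(es$fractions), 1)
})
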