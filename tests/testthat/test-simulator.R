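test_that("electronic noise maps to ~4.7 ADU at G0 for short integration", {
  cfg <- sim_config(dims = c(8L, 8L))
  # 83 e- RMS / 3500 e- per photon * ~200 ADU per photon
  expect_equal(cfg$sigma_adu_g0, 83 / 3500 * (12.4 / 0.062), tolerance = 1e-12)
  expect_equal(round(cfg$sigma_adu_g0, 1), 4.7)
  expect_equal(cfg$adu_per_photon_g0, 200)
  # long-integration noise is 200 e- RMS
  cfg_long <- sim_config(dims = c(8L, 8L), noise_e_rms = 200)
  expect_equal(cfg_long$sigma_adu_g0, 200 / 3500 * 200)
})

test_that("dark frames have the configured pedestal, noise and drift", {
  cfg0 <- sim_config(dims = c(16L, 32L), noise_e_rms = 0, pedestal_spread = 0,
                     seed = 2)
  d0 <- simulate_dark(cfg0, 3, "G0")
  for (f in d0$frames)
    expect_true(all(f$pixels == encode_word("G0", 1000L)))

  cfg <- sim_config(dims = c(64L, 64L), seed = 2,
                    drift = list(type = "ramp", amplitude = 100,
                                 duration = 100))
  d <- simulate_dark(cfg, 101, "G0")
  dec_first <- decode_frame(d$frames[[1]])
  dec_last <- decode_frame(d$frames[[101]])
  rise <- mean(dec_last$adu) - mean(dec_first$adu)
  expect_lt(abs(rise - 100), 0.5)
  # forced gain bits
  expect_true(all(dec_last$gain == 1L))
  dg2 <- simulate_dark(cfg, 2, "G2")
  expect_true(all(decode_frame(dg2$frames[[1]])$gain == 3L))
})

test_that("identical seeds give bit-identical frames", {
  cfg <- sim_config(dims = c(16L, 16L), seed = 33,
                    scene = list(background = 2, spots = NULL))
  a <- simulate_diffraction(cfg, 3)
  b <- simulate_diffraction(cfg, 3)
  for (i in 1:3)
    expect_identical(a$frames[[i]]$pixels, b$frames[[i]]$pixels)
  cfg2 <- sim_config(dims = c(16L, 16L), seed = 34,
                     scene = list(background = 2, spots = NULL))
  c2 <- simulate_diffraction(cfg2, 1)
  expect_false(identical(a$frames[[1]]$pixels, c2$frames[[1]]$pixels))
})

test_that("a zero scene is equivalent to a G0 dark run", {
  cfg <- sim_config(dims = c(16L, 16L), seed = 5,
                    scene = list(background = 0, spots = NULL))
  sim <- simulate_diffraction(cfg, 2)
  expect_true(all(sim$truth[[1]] == 0))
  dec <- decode_frame(sim$frames[[1]])
  expect_true(all(dec$gain == 1L))
  expect_lt(abs(mean(dec$adu) - mean(cfg$calibration$pedestal$g0)), 1)
})

test_that("strong pixels switch gain; occupancy grows with intensity", {
  mk <- function(intensity) sim_config(dims = c(32L, 32L), seed = 6,
    scene = list(background = 1,
                 spots = data.frame(row = 16, col = 16, sigma = 2,
                                    intensity = intensity)))
  # ~5e4 photons in one pixel exceeds the G1 switching threshold
  cfg <- sim_config(dims = c(32L, 32L), seed = 6,
                    scene = list(background = 0,
                                 spots = data.frame(row = 16, col = 16,
                                                    sigma = 0.25,
                                                    intensity = 5e4)))
  sim <- simulate_diffraction(cfg, 1)
  dec <- decode_frame(sim$frames[[1]])
  expect_identical(dec$gain[16, 16], 3L)

  frac_switched <- vapply(c(1e3, 1e4, 1e5), function(s) {
    d <- decode_frame(simulate_diffraction(mk(s), 1)$frames[[1]])
    mean(d$gain > 1L)
  }, numeric(1))
  expect_true(all(diff(frac_switched) >= 0))
})

test_that("converted output matches the simulated expectation within 3 SE", {
  cfg <- sim_config(dims = c(24L, 24L), seed = 8,
                    scene = list(background = 4, spots = NULL))
  n <- 400
  sim <- simulate_diffraction(cfg, n)
  acc <- matrix(0, 24, 24)
  for (f in sim$frames)
    acc <- acc + convert_frame(f, cfg$calibration, unit = "photons")$values
  mean_err <- acc / n - sim$expected[[1]]
  # per-pixel SE: sqrt((lambda + sigma_photon^2) / n)
  se <- sqrt((4 + (cfg$sigma_adu_g0 / 200)^2) / n)
  expect_gt(mean(abs(mean_err) <= 3 * se), 0.99)
  expect_lt(abs(mean(mean_err)), 3 * se / sqrt(24 * 24) * 3)
})

test_that("angular metadata follows speed x frame time", {
  cfg <- sim_config(dims = c(8L, 8L))
  am <- angular_metadata(cfg, 0L)
  expect_equal(am$step, 0.088)
  expect_equal(angular_metadata(cfg, 100L)$start, 8.8)
  cfg0 <- sim_config(dims = c(8L, 8L), rotation_speed = 0)
  expect_equal(angular_metadata(cfg0, 5L)$step, 0)
})
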