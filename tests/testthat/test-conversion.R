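test_that("single-pixel conversion matches the calibration anchors", {
  ped <- rep(1000, 3)
  fac <- c(0.062, 0.707, 8.06)
  # adu == pedestal -> 0 keV
  expect_equal(convert_pixel(encode_word("G0", 1000L), ped, fac), 0)
  # 200 ADU above pedestal at G0 = 12.4 keV = 1 photon at 12.4 keV
  expect_equal(convert_pixel(encode_word("G0", 1200L), ped, fac), 12.4)
  # G2 full scale with default calibration ~ 1e4 photons (within 5%)
  cal <- default_calibration(c(4L, 4L))
  e <- convert_pixel(encode_word("G2", 16383L),
                     c(cal$pedestal$g0[1], cal$pedestal$g1[1], cal$pedestal$g2[1]),
                     c(cal$gain$g0[1], cal$gain$g1[1], cal$gain$g2[1]))
  expect_lt(abs(e / 12.4 - 1e4) / 1e4, 0.05)
  # invalid gain code
  expect_true(is.na(convert_pixel(0x8000L, ped, fac)))
})

test_that("frame conversion is bit-identical to the scalar oracle", {
  set.seed(21)
  dims <- c(24L, 40L)
  cal <- random_calibration(dims)
  # dark frame at exact (integer) pedestals converts to an exact zero frame
  cal0 <- cal
  cal0$pedestal <- lapply(cal0$pedestal, round)
  dark <- raw_frame(matrix(encode_word("G0", as.integer(cal0$pedestal$g0)),
                           dims[1], dims[2]))
  expect_true(all(convert_frame(dark, cal0, unit = "keV")$values == 0))

  # frames mixing all three gains, against the double-loop reference
  for (i in 1:10) {
    fr <- random_raw_frame(dims, valid_only = FALSE)
    got <- convert_frame(fr, cal, unit = "photons", beam_energy = 12.4)
    want <- oracle_convert(fr, cal, unit = "photons", beam_energy = 12.4)
    expect_identical(got$values[!got$mask], want[!got$mask])
    expect_identical(got$mask, is.na(want))
  }
  expect_error(convert_frame(random_raw_frame(c(8L, 8L)), cal), "shape")
  expect_error(convert_frame(dark, cal0, unit = "photons", beam_energy = -1),
               "beam energy")
})

test_that("conversion with a tracker uses the updated G0 pedestal", {
  dims <- c(16L, 16L)
  cal <- default_calibration(dims)
  tr <- pedestal_tracker(cal$pedestal$g0, cal$rms_g0)
  fr <- raw_frame(matrix(encode_word("G0", 1004L), dims[1], dims[2]))
  out <- convert_frame(fr, cal, tracker = tr, unit = "keV")
  tr2 <- attr(out, "tracker")
  # pedestal moved by alpha * 4 ADU, conversion used the moved pedestal
  expect_equal(tr2$pedestal[1, 1], 1000 + 4 / 128)
  expect_equal(out$values[1, 1], (1004 - (1000 + 4 / 128)) * 0.062)
})

test_that("frame summation is linear and accumulates the angular span", {
  ones <- lapply(1:10, function(i)
    photon_frame(matrix(1, 8, 8), angular_span = 0.088))
  out <- sum_frames(ones, 5)
  expect_length(out, 2)
  expect_true(all(out[[1]]$values == 5))
  expect_equal(out[[1]]$angular_span, 0.44)

  set.seed(4)
  rand <- lapply(1:6, function(i)
    photon_frame(matrix(rnorm(64), 8, 8), angular_span = 0.088))
  out <- sum_frames(rand, 3)
  expect_equal(sum(out[[1]]$values) + sum(out[[2]]$values),
               sum(vapply(rand, function(f) sum(f$values), numeric(1))))
  # mask union propagates
  rand[[2]]$values[3, 3] <- NA
  rand[[2]]$mask[3, 3] <- TRUE
  out <- sum_frames(rand, 3)
  expect_true(out[[1]]$mask[3, 3])
  expect_true(is.na(out[[1]]$values[3, 3]))
  expect_error(sum_frames(rand, 4), "divide")
})

test_that("negative-count policies behave as documented", {
  f <- photon_frame(matrix(c(-1, 0, 2, 5), 2, 2))
  expect_equal(apply_negative_policy(f, "keep")$values, f$values)
  expect_equal(as.vector(apply_negative_policy(f, "zero")$values),
               c(0, 0, 2, 5))
  expect_equal(as.vector(apply_negative_policy(f, "offset", 4)$values),
               c(3, 4, 6, 9))
})

test_that("quantization rounds half away from zero within m/2 of the source", {
  f <- photon_frame(matrix(c(3.7, -3.7, 0.5, -0.5, 0.49, 1.5), 2, 3))
  q1 <- quantize(f, m = 1)
  expect_identical(as.vector(q1$k), c(4L, -4L, 1L, -1L, 0L, 2L))
  qh <- quantize(f, m = 1 / 2)
  expect_equal(qh$k[1, 1] * qh$m, 3.5)

  set.seed(14)
  x <- matrix(runif(1e4, -50, 50), 100, 100)
  for (m in c(1 / 8, 1 / 4, 1 / 2, 1, 2, 4, 8)) {
    q <- quantize(photon_frame(x), m = m)
    expect_lte(max(abs(q$k * q$m - x)), m / 2)
  }
  expect_error(quantize(f, m = 0), "positive")
  # sentinels: masked pixels stay masked through the round trip
  f2 <- photon_frame(matrix(c(1, NA, 3, 4), 2, 2))
  q2 <- quantize(f2, m = 1)
  expect_true(is.na(q2$k[2, 1]))
  back <- dequantize(q2)
  expect_true(back$mask[2, 1])
  expect_equal(back$values[1, 1], 1)
})

test_that("fixed-point conversion agrees with the float path to <= 0.5 photon RMS", {
  dims <- c(32L, 64L)
  cal <- default_calibration(dims)
  fp <- fixed_point_calibration(cal, beam_energy = 12.4)

  # constants round-trip within half a quantization step
  back <- fixed_point_constants(fp)
  expect_true(all(abs(back$pedestal$g0 - cal$pedestal$g0) <= 0.5 / 256))
  expect_true(all(abs(back$pedestal$g1 - cal$pedestal$g1) <= 0.5 / 4))
  for (g in c("g0", "g1", "g2"))
    expect_true(all(abs(back$photons_per_adu[[g]] - cal$gain[[g]] / 12.4) <=
                      0.5 / 2^fp$factor_shift[g]))

  # dark frame -> all zeros
  dark <- raw_frame(matrix(encode_word("G0", 1000L), dims[1], dims[2]))
  expect_true(all(convert_frame_fixed_point(dark, fp)$k == 0L))

  # synthetic diffraction: RMS difference vs rounded float path <= 0.5 photon
  cfg <- sim_config(dims = dims, seed = 31,
                    scene = list(background = 3,
                                 spots = data.frame(row = 16, col = 32,
                                                    sigma = 2,
                                                    intensity = 3e4)))
  sim <- simulate_diffraction(cfg, 5)
  fp2 <- fixed_point_calibration(cfg$calibration, 12.4)
  for (fr in sim$frames) {
    kf <- convert_frame_fixed_point(fr, fp2)
    fl <- quantize(convert_frame(fr, cfg$calibration, unit = "photons"), m = 1)
    expect_lte(sqrt(mean((kf$k - fl$k)^2)), 0.5)
  }
})

test_that("dynamic range spans ~2e6 between G0 increment and G2 full scale", {
  cal <- default_calibration(c(2L, 2L))
  inc_g0 <- cal$gain$g0[1, 1] / 12.4          # photons per ADU at G0
  full_g2 <- (16383 - cal$pedestal$g2[1, 1]) * cal$gain$g2[1, 1] / 12.4
  expect_equal(inc_g0, 0.005)
  expect_lt(abs(full_g2 - 1e4) / 1e4, 0.05)
  ratio <- full_g2 / inc_g0
  expect_lt(abs(ratio - 2e6) / 2e6, 0.05)
  expect_identical(dynamic_range_bits(full_g2, inc_g0), 21L)
})
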