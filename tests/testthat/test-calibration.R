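test_that("pedestal estimation recovers mean and RMS of dark readings", {
  dims <- c(24L, 32L)
  const <- lapply(1:100, function(i)
    raw_frame(matrix(encode_word("G0", 1000L), dims[1], dims[2])))
  est <- estimate_pedestal(const, "G0")
  expect_true(all(est$pedestal == 1000))
  expect_true(all(est$rms == 0))
  expect_false(any(est$flagged))

  # Gaussian noise sigma = 4.7 ADU around 1000: mean within 4*sigma/sqrt(N);
  # per-pixel RMS within 15% of sigma (sd of a sample sd at N = 400 is
  # ~3.5%, so the worst of 768 pixels stays well inside)
  set.seed(11)
  n <- 400
  noisy <- lapply(seq_len(n), function(i)
    raw_frame(matrix(encode_word("G0",
      pmin(pmax(round(1000 + rnorm(prod(dims), 0, 4.7)), 0L), 16383L)),
      dims[1], dims[2])))
  est <- estimate_pedestal(noisy, "G0")
  expect_true(all(abs(est$pedestal - 1000) < 4 * 4.7 / sqrt(n)))
  expect_true(all(abs(est$rms - 4.7) / 4.7 < 0.15))

  expect_error(estimate_pedestal(noisy[1], "G0"), "at least 2")
})

test_that("pixels reading a different gain in a pedestal run are flagged", {
  dims <- c(8L, 8L)
  frames <- lapply(1:10, function(i)
    raw_frame(matrix(encode_word("G0", 1000L), dims[1], dims[2])))
  frames[[4]]$pixels[2, 5] <- encode_word("G1", 1000L)
  est <- estimate_pedestal(frames, "G0")
  expect_identical(sum(est$flagged), 1L)
  expect_true(est$flagged[2, 5])
  # the flagged pixel still gets a pedestal from its matching readings
  expect_equal(est$pedestal[2, 5], 1000)
})

test_that("simulator pedestal maps are recovered within 4 sigma/sqrt(N)", {
  cfg <- sim_config(dims = c(24L, 48L), seed = 7)
  n <- 150
  d <- simulate_dark(cfg, n, "G0")
  est <- estimate_pedestal(d$frames, "G0")
  # rounding to integer ADU adds ~0.29 ADU of quantization spread
  tol <- 4 * sqrt(d$sigma_adu^2 + 1 / 12) / sqrt(n)
  expect_true(all(abs(est$pedestal - d$pedestal) < tol))
})

test_that("beam start is found at the first illuminated frame", {
  # drift reaches 100 ADU over a few seconds of frames, so only ~3 ADU
  # accumulate during the 150 dark frames here
  cfg <- sim_config(dims = c(24L, 48L), seed = 9,
                    scene = list(background = 1, spots = NULL),
                    drift = list(type = "ramp", amplitude = 100,
                                 duration = 5000))
  dark <- simulate_dark(cfg, 150, "G0")
  beam <- simulate_diffraction(cfg, 5, start_frame = 150)

  expect_identical(detect_beam_start(c(dark$frames, beam$frames),
                                     cfg$calibration), 150L)
  # all-dark stream, even with drift: no beam
  expect_identical(detect_beam_start(dark$frames, cfg$calibration),
                   NA_integer_)
  # a single bright frame at the start of the stream triggers immediately
  expect_identical(detect_beam_start(beam$frames, cfg$calibration), 150L)
})

test_that("drift tracker follows a 100 ADU ramp with small lag and is gated", {
  # slope 0.01 ADU/frame, alpha = 1/128: EMA lag ~ s(1-a)/a = 1.27 ADU
  cfg <- sim_config(dims = c(16L, 32L), seed = 5,
                    drift = list(type = "ramp", amplitude = 100,
                                 duration = 10000))
  d <- simulate_dark(cfg, 10000, "G0")
  tr <- pedestal_tracker(cfg$calibration$pedestal$g0, cfg$calibration$rms_g0)
  lag <- c()
  for (i in seq_along(d$frames)) {
    upd <- update_pedestal(tr, d$frames[[i]])
    tr <- upd$tracker
    if (i > 6000 && i %% 250 == 0)
      lag <- c(lag, mean(cfg$calibration$pedestal$g0 + d$drift[i] -
                           tr$pedestal))
  }
  expect_lt(mean(lag), 2)
  expect_gt(mean(lag), 0) # the EMA lags behind a rising ramp

  # a frame exactly at the pedestal is a fixed point
  ped <- matrix(1000, 16, 32)
  tr2 <- pedestal_tracker(ped, matrix(4.7, 16, 32))
  fr <- raw_frame(matrix(encode_word("G0", 1000L), 16, 32))
  expect_identical(update_pedestal(tr2, fr)$tracker$pedestal, ped)

  # a 1-photon hit (~200 ADU, ~42 RMS units) is excluded from the update
  hit <- raw_frame(matrix(encode_word("G0", 1200L), 16, 32))
  upd <- update_pedestal(tr2, hit)
  expect_false(any(upd$accepted))
  expect_identical(upd$tracker$pedestal, ped)

  # single-step move never exceeds alpha * k * RMS
  set.seed(3)
  fr3 <- raw_frame(matrix(encode_word("G0",
    pmin(pmax(round(1000 + rnorm(16 * 32, 0, 30)), 0L), 16383L)), 16, 32))
  upd3 <- update_pedestal(tr2, fr3)
  expect_true(all(abs(upd3$tracker$pedestal - ped) <=
                    tr2$alpha * tr2$k * tr2$rms + 1e-12))
})

test_that("calibration files round-trip through HDF5", {
  cal <- random_calibration(c(16L, 24L))
  path <- withr::local_tempfile(fileext = ".h5")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$pedestal, cal$pedestal)
  expect_equal(back$rms_g0, cal$rms_g0)
  expect_equal(back$gain, cal$gain)
})

test_that("calibration constructor validates shapes and ranges", {
  cal <- random_calibration(c(8L, 8L))
  expect_error(calibration(cal$pedestal, cal$rms_g0[1:4, 1:4], cal$gain),
               "dimensions")
  bad <- cal$pedestal
  bad$g0[1, 1] <- 20000
  expect_error(calibration(bad, cal$rms_g0, cal$gain), "range")
  badg <- cal$gain
  badg$g1[2, 2] <- 0
  expect_error(calibration(cal$pedestal, cal$rms_g0, badg), "nonzero")
})
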