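test_that("packetize/assemble is the identity on lossless shuffled streams", {
  set.seed(17)
  frames <- lapply(0:5, function(i)
    random_raw_frame(c(32L, 64L), frame_number = i))
  # 2048 pixels / 256 per packet = 8 packets per frame
  packets <- packetize_frames(frames, payload_pixels = 256L)
  expect_length(packets, 6 * 8)
  expect_error(packetize_frame(frames[[1]], 257L), "divide")
  # one packet per frame is allowed
  expect_length(packetize_frame(frames[[1]], 2048L), 1)

  shuffled <- simulate_link(packets, loss_rate = 0, reorder = TRUE, seed = 2)
  asm <- assemble_frames(shuffled)
  expect_identical(asm$report$frames_complete, 6L)
  expect_identical(asm$report$frames_incomplete, 0L)
  expect_identical(asm$report$packets_lost, 0L)
  for (i in seq_along(frames))
    expect_identical(asm$frames[[i]]$pixels, frames[[i]]$pixels)
})

test_that("reordering preserves the packet multiset; zero loss is identity", {
  set.seed(18)
  frames <- lapply(0:2, function(i) random_raw_frame(c(16L, 16L), frame_number = i))
  packets <- packetize_frames(frames, payload_pixels = 64L)
  out <- simulate_link(packets, loss_rate = 0, reorder = FALSE, seed = 1)
  expect_identical(out, packets)
  reord <- simulate_link(packets, loss_rate = 0, reorder = TRUE, seed = 1)
  key <- function(p) paste(p$frame_number, p$packet_index)
  expect_setequal(vapply(reord, key, character(1)),
                  vapply(packets, key, character(1)))
})

test_that("seeded loss is binomial and accounting is exact", {
  set.seed(19)
  frames <- lapply(0:99, function(i) random_raw_frame(c(16L, 64L), frame_number = i))
  packets <- packetize_frames(frames, payload_pixels = 128L) # 8 per frame
  n <- length(packets)
  p <- 0.01
  surv <- simulate_link(packets, loss_rate = p, seed = 123)
  observed_loss <- n - length(surv)
  expect_lt(abs(observed_loss - n * p), 3 * sqrt(p * (1 - p) * n) + 1)
  # deterministic under the seed
  surv2 <- simulate_link(packets, loss_rate = p, seed = 123)
  expect_identical(length(surv2), length(surv))

  asm <- assemble_frames(surv)
  expect_identical(asm$report$packets_lost, observed_loss)
  expect_identical(asm$report$frames_complete + asm$report$frames_incomplete +
                     length(asm$report$missing_frames), 100L)
})

test_that("a dropped packet masks exactly its pixel region and is reported", {
  frames <- lapply(0:9, function(i) random_raw_frame(c(32L, 64L), frame_number = i))
  packets <- packetize_frames(frames, payload_pixels = 256L)
  # drop exactly packet 0 of frame 7
  drop <- vapply(packets, function(p)
    p$frame_number == 7L && p$packet_index == 0L, logical(1))
  asm <- assemble_frames(packets[!drop])
  expect_identical(asm$report$frames_incomplete, 1L)
  expect_identical(asm$report$packets_lost, 1L)
  expect_identical(asm$report$missing, list(`7` = 0L))
  f7 <- asm$frames[[8]]
  expect_identical(sum(is.na(f7$pixels)), 256L)
  # the masked pixels are the first 256 in row-major order
  expect_true(all(is.na(t(f7$pixels))[1:256]))

  # empty stream
  empty <- assemble_frames(list())
  expect_length(empty$frames, 0)
  expect_identical(empty$report$frames_complete, 0L)
})

test_that("duplicate packets keep the first copy and are counted", {
  fr <- random_raw_frame(c(16L, 16L), frame_number = 0L)
  packets <- packetize_frame(fr, 64L)
  dup <- packets[[2]]
  dup$payload <- rep(0L, 64)
  asm <- assemble_frames(c(packets, list(dup)))
  expect_identical(asm$report$duplicates, 1L)
  expect_identical(asm$frames[[1]]$pixels, fr$pixels)
})

test_that("packet streams round-trip through the stream file dialect", {
  set.seed(20)
  frames <- lapply(0:2, function(i) random_raw_frame(c(16L, 32L), frame_number = i))
  packets <- packetize_frames(frames, payload_pixels = 128L)
  path <- withr::local_tempfile()
  write_packet_stream(packets, path)
  back <- read_packet_stream(path)
  expect_length(back, length(packets))
  for (i in seq_along(packets)) {
    expect_identical(back[[i]]$payload, packets[[i]]$payload)
    expect_identical(back[[i]]$packet_index, packets[[i]]$packet_index)
  }
  asm <- assemble_frames(back)
  expect_identical(asm$frames[[1]]$pixels, frames[[1]]$pixels)
})
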