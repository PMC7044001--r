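# Independent reference implementations used as oracles, deliberately
# written as plain per-pixel / per-bit loops so they share no code path
# with the vectorized implementations they check.

# Scalar reference of the conversion procedure: decode gain bits, subtract
# that gain's pedestal, multiply by that gain's factor, one pixel at a time.
oracle_convert <- function(frame, calib, unit = "photons", beam_energy = 12.4,
                           ped_g0 = NULL) {
  d <- dim(frame$pixels)
  out <- matrix(NA_real_, d[1], d[2])
  p0 <- if (is.null(ped_g0)) calib$pedestal$g0 else ped_g0
  for (r in seq_len(d[1])) {
    for (cl in seq_len(d[2])) {
      w <- frame$pixels[r, cl]
      if (is.na(w)) next
      g <- w %/% 16384L
      a <- w - g * 16384L
      gi <- c(1L, 2L, NA_integer_, 3L)[g + 1L]
      if (is.na(gi)) next
      p <- if (gi == 1L) p0[r, cl]
           else if (gi == 2L) calib$pedestal$g1[r, cl]
           else calib$pedestal$g2[r, cl]
      f <- if (gi == 1L) calib$gain$g0[r, cl]
           else if (gi == 2L) calib$gain$g1[r, cl]
           else calib$gain$g2[r, cl]
      e <- (a - p) * f
      out[r, cl] <- if (unit == "photons") e / beam_energy else e
    }
  }
  out
}

# Naive per-bit loop over the bit-plane transposition.
oracle_bitshuffle <- function(bytes, elem_size, order = "msb") {
  n_elem <- length(bytes) %/% elem_size
  n_planes <- elem_size * 8L
  # bit b (0 = LSB) of value for element e, little-endian bytes
  value_bit <- function(e, b) {
    byte <- as.integer(bytes[(e - 1L) * elem_size + b %/% 8L + 1L])
    (byte %/% 2L^(b %% 8L)) %% 2L
  }
  out <- raw(length(bytes))
  for (p in seq_len(n_planes) - 1L) {
    b <- if (order == "msb") n_planes - 1L - p
         else (p %/% 8L) * 8L + (7L - p %% 8L)
    for (j in seq_len(n_elem %/% 8L) - 1L) {
      acc <- 0L
      for (k in 0:7) {
        acc <- acc * 2L + value_bit(j * 8L + k + 1L, b)
      }
      out[p * (n_elem %/% 8L) + j + 1L] <- as.raw(acc)
    }
  }
  out
}

random_raw_frame <- function(dims = c(32L, 64L), valid_only = TRUE,
                             frame_number = 0L) {
  codes <- if (valid_only) c(0L, 1L, 3L) else 0:3
  words <- sample(codes, prod(dims), replace = TRUE) * 16384L +
    sample(0:16383, prod(dims), replace = TRUE)
  raw_frame(matrix(words, dims[1], dims[2]), frame_number = frame_number)
}

random_calibration <- function(dims = c(32L, 64L)) {
  rmat <- function(lo, hi) matrix(stats::runif(prod(dims), lo, hi),
                                  dims[1], dims[2])
  calibration(
    pedestal = list(g0 = rmat(900, 1100), g1 = rmat(900, 1100),
                    g2 = rmat(900, 1100)),
    rms_g0 = rmat(3, 6),
    gain = list(g0 = rmat(0.05, 0.07), g1 = rmat(0.6, 0.8),
                g2 = rmat(7, 9))
  )
}

# The standard compression fixture: one frame through the full detector
# path (Poisson photons from a radially falling diffuse background with a
# water ring plus Bragg spots, long-integration electronic noise of 200 e-,
# raw gain+ADU words, conversion to photons), so pixel values carry the
# fractional noise content of converted beamline images.
standard_fixture_frame <- function(dims = c(128L, 256L), seed = 42L) {
  rr <- row(matrix(0, dims[1], dims[2]))
  cc <- col(matrix(0, dims[1], dims[2]))
  rad <- sqrt((rr - dims[1] / 2)^2 + (cc - dims[2] / 2)^2) / (dims[2] / 2)
  bg <- 0.5 + 5 * exp(-3 * rad^2) + 2 * exp(-((rad - 0.7) / 0.08)^2)
  set.seed(seed)
  spots <- data.frame(row = sample(10:(dims[1] - 10), 8),
                      col = sample(10:(dims[2] - 10), 8),
                      sigma = 1.5, intensity = 3000)
  cfg <- sim_config(dims = dims, seed = seed, noise_e_rms = 200,
                    scene = list(background = bg, spots = spots))
  sim <- simulate_diffraction(cfg, 1)
  convert_frame(sim$frames[[1]], cfg$calibration, unit = "photons")
}

ref_script <- function() {
  p <- system.file("ref", "bshuf_ref.py", package = "jfproc")
  stopifnot(nzchar(p))
  p
}

# Run the NumPy/numcodecs reference implementation on raw bytes.
run_reference <- function(mode, input, elem_size, codec = NULL,
                          block_bytes = NULL) {
  fin <- tempfile(); fout <- tempfile()
  on.exit(unlink(c(fin, fout)))
  writeBin(input, fin)
  args <- c(ref_script(), mode, elem_size, codec, block_bytes)
  status <- system2("python", shQuote(as.character(args)),
                    stdin = fin, stdout = fout)
  stopifnot(status == 0)
  readBin(fout, "raw", file.info(fout)$size)
}
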