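#' Data rate of a single module
#'
#' One module produces `524288 pixels x 16 bit x frame_rate`; at 1.1 kHz
#' that is 1.15 GB/s (9.23 Gbit/s, close to the theoretical bandwidth of a
#' 10 GbE link), and 2.30 GB/s at 2.2 kHz with the second link enabled.
#' GB and Gbit are decimal (10^9) throughout.
#'
#' @param frame_rate Frames per second.
#' @return List with `gb_s` (GB/s) and `gbit_s` (Gbit/s), exact values.
#' @export
module_data_rate <- function(frame_rate) {
  stopifnot(frame_rate > 0)
  bits <- prod(module_dims()) * 16 * frame_rate
  list(gb_s = bits / 8 / 1e9, gbit_s = bits / 1e9)
}

#' Data rate of a multi-module detector
#'
#' @param n_modules Number of modules (8 for the 4 Mpixel class, 20 for the
#'   10 Mpixel class, 32 for the 16 Mpixel class).
#' @param frame_rate Frames per second.
#' @return Detector data rate in GB/s (exact; display rounding is left to
#'   the caller).
#' @export
detector_data_rate <- function(n_modules, frame_rate) {
  stopifnot(n_modules >= 1)
  n_modules * module_data_rate(frame_rate)$gb_s
}

#' Memory traffic required by the conversion
#'
#' Converting one pixel moves 224 bits through memory: 16 bits of raw pixel
#' in, 16 bits of converted pixel out, and 192 bits of conversion constants
#' (six 32-bit values: pedestal and gain factor for the three gain levels).
#' Pedestal drift tracking adds one fetched constant (the G0 pedestal RMS)
#' and a write of the updated G0 pedestal: 64 more bits, 288 in total.
#'
#' @param n_modules Number of modules.
#' @param frame_rate Frames per second.
#' @param drift Include the drift-tracking traffic.
#' @return Required memory bandwidth in GB/s.
#' @export
conversion_bandwidth <- function(n_modules, frame_rate, drift = FALSE) {
  stopifnot(n_modules >= 1, frame_rate > 0)
  bits_per_px <- if (drift) 288 else 224
  pixel_rate <- n_modules * prod(module_dims()) * frame_rate
  pixel_rate * bits_per_px / 8 / 1e9
}

#' Integer bits needed for a linear photon scale
#'
#' The smallest increment a pixel can encode is 1 ADU at G0 (about 0.005
#' photons at 12.4 keV) and the largest is G2 saturation (about 10^4
#' photons); the ratio of 2 x 10^6 needs a 21-bit integer.
#'
#' @param max_photons Largest representable value.
#' @param min_increment Smallest representable increment.
#' @return `ceiling(log2(max / min))`, an integer bit count.
#' @export
dynamic_range_bits <- function(max_photons, min_increment) {
  stopifnot(max_photons >= min_increment, min_increment > 0)
  as.integer(ceiling(log2(max_photons / min_increment)))
}

#' Rotation bookkeeping: angular step and image count
#'
#' @param rotation_speed Degrees per second.
#' @param frame_time Seconds per frame.
#' @param total_range Total rotation in degrees.
#' @return List with `step` (degrees per image) and `n_images`
#'   (`floor(total_range / step)`); 100 deg/s at 880 microseconds over 180
#'   degrees gives 0.088 deg and 2045 images.
#' @export
rotation_bookkeeping <- function(rotation_speed, frame_time, total_range) {
  stopifnot(rotation_speed > 0, frame_time > 0, total_range > 0)
  step <- rotation_speed * frame_time
  list(step = step, n_images = as.integer(floor(total_range / step)))
}

#' Data-rate summary table for detector systems
#'
#' @param systems Data frame with columns `name`, `mpixel`, `n_modules`,
#'   `frame_rate_khz`; defaults to the three large-format systems operated
#'   or planned for macromolecular crystallography.
#' @return The table with a `gb_s` column (rounded to one decimal for
#'   display, like the published summaries).
#' @export
rates_table <- function(systems = NULL) {
  if (is.null(systems))
    systems <- data.frame(
      name = c("XFEL 16M", "SLS 4M (2018)", "SLS 10M (2021)"),
      mpixel = c(16, 4, 10),
      n_modules = c(32L, 8L, 20L),
      frame_rate_khz = c(0.1, 1.1, 2.2))
  systems$gb_s <- round(vapply(seq_len(nrow(systems)), function(i)
    detector_data_rate(systems$n_modules[i], systems$frame_rate_khz[i] * 1000),
    numeric(1)), 1)
  systems
}
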