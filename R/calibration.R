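#' Calibration constants for a module
#'
#' Per-pixel pedestal maps (ADU) for the three gain levels, the G0 pedestal
#' RMS map (ADU, used to gate drift updates), and per-pixel gain factors
#' (keV/ADU).  Gain factors are inputs from a calibration file: they are
#' measured before detector operation, not estimated here.
#'
#' @param pedestal Named list of three numeric matrices `g0`, `g1`, `g2`
#'   (ADU, values in `[0, 16383]`).
#' @param rms_g0 Numeric matrix of G0 pedestal RMS (ADU, >= 0).
#' @param gain Named list of three numeric matrices `g0`, `g1`, `g2`
#'   (keV/ADU, nonzero; real G1/G2 slopes may be negative).
#' @return An object of class `jf_calibration`.
#' @export
calibration <- function(pedestal, rms_g0, gain) {
  stopifnot(all(c("g0", "g1", "g2") %in% names(pedestal)),
            all(c("g0", "g1", "g2") %in% names(gain)))
  d <- dim(pedestal$g0)
  for (m in c(pedestal, list(rms_g0), gain))
    if (!identical(dim(m), d)) stop("all calibration maps must share dimensions")
  for (m in pedestal)
    if (any(m < 0 | m > 16383, na.rm = TRUE)) stop("pedestal out of ADU range")
  if (any(rms_g0 < 0, na.rm = TRUE)) stop("negative pedestal RMS")
  for (m in gain)
    if (any(m == 0, na.rm = TRUE)) stop("gain factor must be nonzero")
  structure(list(pedestal = pedestal[c("g0", "g1", "g2")],
                 rms_g0 = rms_g0,
                 gain = gain[c("g0", "g1", "g2")]),
            class = "jf_calibration")
}

#' @export
print.jf_calibration <- function(x, ...) {
  d <- dim(x$pedestal$g0)
  cat(sprintf("<jf_calibration> %d x %d pixels\n", d[1], d[2]))
  cat(sprintf("  pedestal means (ADU): G0 %.1f, G1 %.1f, G2 %.1f\n",
              mean(x$pedestal$g0), mean(x$pedestal$g1), mean(x$pedestal$g2)))
  cat(sprintf("  gain factors (keV/ADU): G0 %.4g, G1 %.4g, G2 %.4g\n",
              mean(x$gain$g0), mean(x$gain$g1), mean(x$gain$g2)))
  invisible(x)
}

#' Default synthetic calibration constants
#'
#' Constants anchored to the two dynamic-range endpoints of the detector at
#' 12.4 keV: 1 ADU at G0 is about 0.005 photons (G0 factor 0.062 keV/ADU,
#' i.e. roughly 200 ADU per photon), and G2 full scale is about 10^4
#' photons.  The G1 factor is the geometric mean of the two.
#'
#' @param dims Frame dimensions, default [module_dims()].
#' @param pedestal_adu Mean pedestal per gain level (ADU), length 3.
#' @param rms_adu G0 pedestal RMS (ADU); 4.7 ADU corresponds to the 83
#'   electron RMS short-integration noise at 200 ADU/photon.
#' @param gain_g0 G0 gain factor in keV/ADU.
#' @param g2_full_scale_kev Energy at G2 saturation (keV); 1.24e5 keV is
#'   10^4 photons of 12.4 keV.
#' @return A [calibration()] object with spatially uniform maps.
#' @export
default_calibration <- function(dims = module_dims(),
                                pedestal_adu = c(1000, 1000, 1000),
                                rms_adu = 4.743,
                                gain_g0 = 0.062,
                                g2_full_scale_kev = 1.24e5) {
  const <- function(v) matrix(v, dims[1], dims[2])
  gain_g2 <- g2_full_scale_kev / (16383 - pedestal_adu[3])
  gain_g1 <- sqrt(gain_g0 * gain_g2)
  calibration(
    pedestal = list(g0 = const(pedestal_adu[1]), g1 = const(pedestal_adu[2]),
                    g2 = const(pedestal_adu[3])),
    rms_g0 = const(rms_adu),
    gain = list(g0 = const(gain_g0), g1 = const(gain_g1), g2 = const(gain_g2))
  )
}

#' Estimate per-pixel pedestals from dark frames
#'
#' Pedestal = the mean reading of each pixel in the absence of x-rays, per
#' gain level; the per-pixel standard deviation is kept as the pedestal
#' RMS.  Pedestals for the low gains (G1, G2) come from dedicated runs with
#' the detector forced to those gains; the G0 pedestal comes from dark
#' frames at the start of the exposure.  Pixels that ever report a gain
#' other than the requested one are flagged (their statistics use only the
#' matching readings); pixels that never match get `NA` and a flag.
#'
#' @param frames List of [raw_frame()] objects (>= 2).
#' @param gain Requested gain level, `"G0"`, `"G1"` or `"G2"`.
#' @return List with `pedestal` (matrix, ADU), `rms` (matrix, ADU),
#'   `flagged` (logical matrix) and `n_frames`.
#' @export
estimate_pedestal <- function(frames, gain = "G0") {
  if (length(frames) < 2) stop("need at least 2 dark frames")
  gi <- match(gain, gain_levels())
  if (is.na(gi)) stop("unknown gain level")
  d <- dim(frames[[1]]$pixels)
  s <- s2 <- n <- matrix(0, d[1], d[2])
  mismatch <- matrix(FALSE, d[1], d[2])
  for (f in frames) {
    dec <- decode_frame(f)
    ok <- !is.na(dec$gain) & dec$gain == gi
    mismatch <- mismatch | !ok
    a <- ifelse(ok, as.double(dec$adu), 0)
    s <- s + a
    s2 <- s2 + a * a
    n <- n + ok
  }
  mean_map <- ifelse(n > 0, s / n, NA_real_)
  var_map <- ifelse(n > 1, pmax(0, (s2 - s * s / n) / (n - 1)), NA_real_)
  list(pedestal = mean_map, rms = sqrt(var_map),
       flagged = mismatch, n_frames = length(frames))
}

#' Detect the first illuminated frame in a stream
#'
#' The acquisition is started before the shutter opens, so the first frames
#' are dark and usable for the G0 pedestal.  A frame counts as illuminated
#' when its total converted signal exceeds the rolling dark baseline by
#' `factor` times the expected dark total noise (derived from the G0
#' pedestal RMS map).
#'
#' A frame is illuminated when its total exceeds `factor` times the rolling
#' baseline of preceding totals; because pedestal drift inflates dark
#' totals slowly, the baseline tracks it and only a genuine jump triggers.
#' Two cold-start guards keep the first frames from false-triggering: a
#' minimum per-pixel signal (`min_signal`, photons/pixel) and the expected
#' dark-total noise derived from the G0 pedestal RMS map.
#'
#' @param frames List of [raw_frame()] objects (in acquisition order).
#' @param calib A [calibration()] object.
#' @param factor Threshold multiplier, default 5.
#' @param window Number of preceding frames in the rolling baseline.
#' @param min_signal Smallest mean signal (photons/pixel) that counts as
#'   illumination.
#' @param beam_energy Photon energy in keV used to express totals in photons.
#' @return The `frame_number` of the first illuminated frame, or
#'   `NA_integer_` if the stream stays dark.
#' @export
detect_beam_start <- function(frames, calib, factor = 5, window = 100,
                              min_signal = 0.01, beam_energy = 12.4) {
  sigma_ph <- calib$rms_g0 * abs(calib$gain$g0) / beam_energy
  total_sd <- sqrt(sum(sigma_ph^2))
  n_px <- length(sigma_ph)
  totals <- numeric(length(frames))
  for (i in seq_along(frames)) {
    pf <- convert_frame(frames[[i]], calib, unit = "photons",
                        beam_energy = beam_energy)
    totals[i] <- sum(pf$values, na.rm = TRUE)
    base <- if (i == 1) 0 else mean(totals[max(1, i - window):(i - 1)])
    threshold <- max(factor * base, min_signal * n_px, factor * total_sd)
    if (totals[i] > threshold)
      return(frames[[i]]$frame_number)
  }
  NA_integer_
}

#' G0 pedestal drift tracker
#'
#' Pedestals depend on system temperature and drift during the exposure (up
#' to 100 ADU, 2.5 keV, a fraction of a photon).  The tracker follows the
#' drift with an exponential moving average over dark-looking G0 readings:
#' a pixel is accepted into the update when its reading lies within
#' `k` RMS of the current pedestal, so photon hits (about 200 ADU, i.e.
#' roughly 42 RMS units above pedestal) are excluded.  alpha = 1/128 is a
#' power of two, friendly to the 22-bit fixed-point pedestal with 8
#' fractional bits used in the fixed-point conversion path.
#'
#' @param pedestal Initial G0 pedestal map (ADU), e.g. from
#'   [estimate_pedestal()].
#' @param rms G0 pedestal RMS map (ADU).
#' @param alpha Update weight in (0,1), default 1/128.
#' @param k Acceptance window half-width in RMS units, default 3.
#' @return An object of class `jf_tracker`.
#' @export
pedestal_tracker <- function(pedestal, rms, alpha = 1 / 128, k = 3) {
  stopifnot(alpha > 0, alpha < 1, k > 0, identical(dim(pedestal), dim(rms)))
  structure(list(pedestal = pedestal, rms = rms,
                 alpha = alpha, k = k, n_updates = 0L),
            class = "jf_tracker")
}

#' @export
print.jf_tracker <- function(x, ...) {
  cat(sprintf(
    "<jf_tracker> alpha = 1/%g, k = %g RMS, %d frames tracked, mean pedestal %.2f ADU\n",
    1 / x$alpha, x$k, x$n_updates, mean(x$pedestal)))
  invisible(x)
}

#' Update the pedestal tracker with one frame
#'
#' For pixels reading G0 with `|ADU - pedestal| <= k * RMS` the pedestal
#' moves by `alpha * (ADU - pedestal)`; all other pixels are unchanged.  A
#' single update therefore never moves a pedestal by more than
#' `alpha * k * RMS`.
#'
#' @param tracker A [pedestal_tracker()].
#' @param frame A [raw_frame()].
#' @return List with the updated `tracker` and the logical `accepted` map.
#' @export
update_pedestal <- function(tracker, frame) {
  stopifnot(inherits(tracker, "jf_tracker"), inherits(frame, "jf_raw_frame"))
  dec <- decode_frame(frame)
  accepted <- !is.na(dec$gain) & dec$gain == 1L &
    abs(dec$adu - tracker$pedestal) <= tracker$k * tracker$rms
  delta <- tracker$alpha * (dec$adu - tracker$pedestal)
  tracker$pedestal <- tracker$pedestal + ifelse(accepted, delta, 0)
  tracker$pedestal <- pmin(pmax(tracker$pedestal, 0), 16383)
  tracker$n_updates <- tracker$n_updates + 1L
  list(tracker = tracker, accepted = accepted)
}

CALIB_MAP_NAMES <- c("pedestal_g0", "pedestal_g1", "pedestal_g2", "rms_g0",
                     "gain_g0", "gain_g1", "gain_g2")

#' Write calibration constants to an HDF5 file
#'
#' One HDF5 container holding the seven per-pixel maps as float64 datasets
#' `/calibration/{pedestal_g0,pedestal_g1,pedestal_g2,rms_g0,gain_g0,
#' gain_g1,gain_g2}`.
#'
#' @param calib A [calibration()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "jf_calibration"))
  maps <- list(calib$pedestal$g0, calib$pedestal$g1, calib$pedestal$g2,
               calib$rms_g0, calib$gain$g0, calib$gain$g1, calib$gain$g2)
  .Call(C_h5_write_map_file, path.expand(path), "calibration",
        CALIB_MAP_NAMES, maps)
  invisible(path)
}

#' Read calibration constants from an HDF5 file
#'
#' @param path File written by [write_calibration()].
#' @return A [calibration()] object.
#' @export
read_calibration <- function(path) {
  maps <- .Call(C_h5_read_map_file, path.expand(path), "calibration")
  if (!all(CALIB_MAP_NAMES %in% names(maps)))
    stop("calibration file is missing maps")
  calibration(
    pedestal = list(g0 = maps$pedestal_g0, g1 = maps$pedestal_g1,
                    g2 = maps$pedestal_g2),
    rms_g0 = maps$rms_g0,
    gain = list(g0 = maps$gain_g0, g1 = maps$gain_g1, g2 = maps$gain_g2)
  )
}
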