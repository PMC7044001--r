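#' Sentinel codes for quantized frames
#'
#' Masked pixels are stored as -2^31 (the bit pattern of R's `NA_integer_`,
#' so masked pixels simply appear as `NA` in R) and saturated pixels as
#' 2^31 - 1.
#'
#' @return Named integer-like list with `masked` and `saturated`.
#' @export
quantized_sentinels <- function() {
  list(masked = NA_integer_, saturated = 2147483647L)
}

#' Converted photon/energy frame
#'
#' Real-valued image after pedestal subtraction and gain scaling, in keV or
#' photon units, with a validity mask and the angular span covered during
#' the exposure.
#'
#' @param values Numeric matrix (keV or photons); `NA` where masked.
#' @param unit `"keV"` or `"photons"`.
#' @param mask Logical matrix of invalid pixels; default from `NA` values.
#' @param angular_span Rotation covered by this image in degrees.
#' @param expanded Whether inter-chip large pixels have been expanded.
#' @return An object of class `jf_photon_frame`.
#' @export
photon_frame <- function(values, unit = c("photons", "keV"), mask = NULL,
                         angular_span = NA_real_, expanded = FALSE) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values))
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(identical(dim(mask), dim(values)))
  if (any(!is.finite(values[!mask])))
    stop("non-finite values outside the mask")
  structure(list(values = values, unit = unit, mask = mask,
                 angular_span = angular_span, expanded = expanded),
            class = "jf_photon_frame")
}

#' @export
print.jf_photon_frame <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<jf_photon_frame> %d x %d [%s]%s\n", d[1], d[2], x$unit,
              if (x$expanded) " (expanded)" else ""))
  cat(sprintf("  total %.4g, max %.4g, %d masked, %.3f deg span\n",
              sum(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(x$mask), x$angular_span))
  invisible(x)
}

#' @export
dim.jf_photon_frame <- function(x) dim(x$values)

#' Convert a single pixel word to deposited energy
#'
#' The conversion per pixel: decode the gain level, subtract that gain's
#' pedestal, multiply by that gain's conversion factor --
#' `energy = (adu - pedestal[gain]) * gain_factor[gain]` in keV.
#'
#' @param word Integer pixel word.
#' @param pedestal Numeric length-3 vector of pedestals (G0, G1, G2) in ADU.
#' @param gain_factor Numeric length-3 vector of factors in keV/ADU.
#' @return Energy in keV, or `NA` for the invalid gain code.
#' @examples
#' convert_pixel(encode_word("G0", 1200L), rep(1000, 3), c(0.062, 0.7, 8))
#' @export
convert_pixel <- function(word, pedestal, gain_factor) {
  dec <- decode_word(word)
  gi <- match(dec$gain, gain_levels())
  ifelse(is.na(gi), NA_real_,
         (dec$adu - pedestal[gi]) * gain_factor[gi])
}

#' Convert a raw frame to energy or photon counts
#'
#' Element-wise pedestal subtraction and gain scaling using each pixel's
#' own gain level, optionally followed by division by the beam energy to
#' express the image in photons.  When a [pedestal_tracker()] is supplied,
#' the tracker is first updated with this frame and its updated G0 pedestal
#' replaces the static calibration pedestal (G0 pedestal drift tracking).
#'
#' @param frame A [raw_frame()].
#' @param calib A [calibration()] object.
#' @param tracker Optional [pedestal_tracker()]; pass the value back in via
#'   `convert_frame(...)$tracker` style bookkeeping from [run_convert()],
#'   or use [update_pedestal()] manually.
#' @param unit `"photons"` or `"keV"`.
#' @param beam_energy Photon energy in keV (required for photon units).
#' @param angular_span Angular span covered by the frame, in degrees.
#' @return A [photon_frame()]; when `tracker` is given, the updated tracker
#'   is attached as attribute `"tracker"`.
#' @export
convert_frame <- function(frame, calib, tracker = NULL,
                          unit = c("photons", "keV"), beam_energy = 12.4,
                          angular_span = NA_real_) {
  unit <- match.arg(unit)
  stopifnot(inherits(frame, "jf_raw_frame"), inherits(calib, "jf_calibration"))
  if (!identical(dim(frame$pixels), dim(calib$pedestal$g0)))
    stop("calibration shape does not match the frame")
  if (unit == "photons" && (!is.numeric(beam_energy) || beam_energy <= 0))
    stop("photon units require a positive beam energy")

  dec <- decode_frame(frame)
  ped_g0 <- calib$pedestal$g0
  if (!is.null(tracker)) {
    upd <- update_pedestal(tracker, frame)
    tracker <- upd$tracker
    ped_g0 <- tracker$pedestal
  }
  P <- ped_g0
  Fc <- calib$gain$g0
  g1 <- !is.na(dec$gain) & dec$gain == 2L
  g2 <- !is.na(dec$gain) & dec$gain == 3L
  P[g1] <- calib$pedestal$g1[g1]
  P[g2] <- calib$pedestal$g2[g2]
  Fc[g1] <- calib$gain$g1[g1]
  Fc[g2] <- calib$gain$g2[g2]

  e <- (dec$adu - P) * Fc
  if (unit == "photons") e <- e / beam_energy
  e[dec$invalid] <- NA_real_
  out <- photon_frame(e, unit = unit, mask = dec$invalid,
                      angular_span = angular_span)
  if (!is.null(tracker)) attr(out, "tracker") <- tracker
  out
}

#' Sum groups of consecutive converted frames
#'
#' Summation reduces the output frame rate and coarsens the angular
#' slicing: summing five 0.088 deg frames yields 0.44 deg per output image.
#' Masks are propagated as the union; angular spans add.
#'
#' @param frames List of [photon_frame()] objects with equal shape and unit.
#' @param n Number of consecutive frames per output image; must divide
#'   `length(frames)`.
#' @return List of `length(frames) / n` summed [photon_frame()] objects.
#' @export
sum_frames <- function(frames, n) {
  stopifnot(length(frames) >= 1, n >= 1)
  if (length(frames) %% n != 0)
    stop("n must divide the number of frames")
  u <- frames[[1]]$unit
  d <- dim(frames[[1]]$values)
  ex <- frames[[1]]$expanded
  out <- vector("list", length(frames) %/% n)
  for (g in seq_along(out)) {
    idx <- ((g - 1) * n + 1):(g * n)
    acc <- matrix(0, d[1], d[2])
    mask <- matrix(FALSE, d[1], d[2])
    span <- 0
    for (i in idx) {
      f <- frames[[i]]
      if (!identical(dim(f$values), d) || f$unit != u || f$expanded != ex)
        stop("frames differ in shape, unit or expansion state")
      v <- f$values
      v[f$mask] <- 0
      acc <- acc + v
      mask <- mask | f$mask
      span <- span + (if (is.na(f$angular_span)) 0 else f$angular_span)
    }
    acc[mask] <- NA_real_
    out[[g]] <- photon_frame(acc, unit = u, mask = mask,
                             angular_span = span, expanded = ex)
  }
  out
}

#' Apply a negative-count policy to a converted frame
#'
#' Pedestal noise can make dark pixels slightly negative after conversion
#' (e.g. -1 photon).  Rotation-method processing programs reject negative
#' counts, so the pipeline can keep them, clip them to zero, or offset all
#' pixel values by a constant.
#'
#' @param frame A [photon_frame()].
#' @param policy `"keep"`, `"zero"` or `"offset"`.
#' @param offset Constant added under the `"offset"` policy.
#' @return The adjusted [photon_frame()].
#' @export
apply_negative_policy <- function(frame, policy = c("keep", "zero", "offset"),
                                  offset = 0) {
  policy <- match.arg(policy)
  v <- frame$values
  if (policy == "zero") v <- pmax(v, 0)
  if (policy == "offset") v <- v + offset
  v[frame$mask] <- NA_real_
  frame$values <- v
  frame
}

#' Quantized (rounded) frame
#'
#' Integer image at scale `m` photons: stored value `k` represents
#' `k * m` photons, so `|k * m - x| <= m/2` off the sentinels.
#'
#' @param k Integer matrix; `NA` = masked (stored as -2^31),
#'   `2^31 - 1` = saturated.
#' @param m Rounding multiple in photons.
#' @param angular_span Angular span covered, degrees.
#' @param negative_policy Policy applied before rounding (metadata).
#' @return An object of class `jf_quantized_frame`.
#' @export
quantized_frame <- function(k, m, angular_span = NA_real_,
                            negative_policy = "keep") {
  stopifnot(is.matrix(k), m > 0)
  storage.mode(k) <- "integer"
  structure(list(k = k, m = m, angular_span = angular_span,
                 negative_policy = negative_policy),
            class = "jf_quantized_frame")
}

#' @export
print.jf_quantized_frame <- function(x, ...) {
  d <- dim(x$k)
  cat(sprintf("<jf_quantized_frame> %d x %d, m = %g photons, %d masked\n",
              d[1], d[2], x$m, sum(is.na(x$k))))
  invisible(x)
}

#' @export
dim.jf_quantized_frame <- function(x) dim(x$k)

#' Round a photon frame to a multiple of the photon count
#'
#' `k = round(x / m)` with ties away from zero, so +x and -x stay symmetric
#' under the `"keep"` negative policy.  Useful multiples for rotation
#' crystallography range from 1/8 to 8 photons; rounding coarser than one
#' photon costs data quality, finer than one photon mostly costs bits.
#'
#' @param frame A [photon_frame()] in photon units.
#' @param m Rounding multiple in photons (> 0).
#' @param negative_policy Applied via [apply_negative_policy()] first.
#' @param offset Offset constant for the `"offset"` policy.
#' @return A [quantized_frame()].
#' @export
quantize <- function(frame, m = 1, negative_policy = "keep", offset = 0) {
  stopifnot(inherits(frame, "jf_photon_frame"))
  if (!is.numeric(m) || length(m) != 1 || m <= 0)
    stop("rounding multiple m must be positive")
  if (frame$unit != "photons")
    stop("quantization expects a frame in photon units")
  frame <- apply_negative_policy(frame, negative_policy, offset)
  x <- frame$values / m
  k <- sign(x) * floor(abs(x) + 0.5)
  sat <- !is.na(k) & abs(k) > 2147483646
  k[sat] <- 2147483647
  k[frame$mask] <- NA_real_
  out <- quantized_frame(matrix(as.integer(k), nrow(x), ncol(x)), m,
                         angular_span = frame$angular_span,
                         negative_policy = negative_policy)
  attr(out, "n_saturated") <- sum(sat)
  out
}

#' Reconstruct photon values from a quantized frame
#'
#' @param qframe A [quantized_frame()].
#' @return A [photon_frame()] with values `k * m`.
#' @export
dequantize <- function(qframe) {
  stopifnot(inherits(qframe, "jf_quantized_frame"))
  k <- qframe$k
  sat <- !is.na(k) & k == quantized_sentinels()$saturated
  v <- k * qframe$m
  v[sat] <- NA_real_
  photon_frame(v, unit = "photons", mask = is.na(k) | sat,
               angular_span = qframe$angular_span)
}
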