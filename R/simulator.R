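#' Simulation configuration
#'
#' Defines the synthetic detector: electronics (electrons per 12.4 keV
#' photon, electronic noise RMS in electrons), calibration constants (the
#' default [default_calibration()] with per-pixel pedestal variation),
#' automatic gain switching thresholds, pedestal drift, the diffraction
#' scene, and rotation timing.  Defaults follow the detector's published
#' characteristics: 3500 electrons per 12.4 keV photon, 83 electrons RMS
#' noise at short integration (200 at the long integration used for
#' crystallography), about 200 ADU per photon at G0, frame time 880
#' microseconds (1.1 kHz) and 100 deg/s rotation (0.088 deg per image).
#'
#' @param dims Frame dimensions (desk-scale work may use smaller frames).
#' @param beam_energy Photon energy, keV.
#' @param e_per_photon Electrons generated per photon of `beam_energy`.
#' @param noise_e_rms Electronic noise RMS, electrons.
#' @param pedestal_adu Mean pedestals per gain (ADU), length 3.
#' @param pedestal_spread Half-width of the uniform per-pixel pedestal
#'   variation (ADU).
#' @param rms_adu Nominal G0 pedestal RMS entered in the calibration.
#' @param gain_switch_frac Gain switches when the current gain's reading
#'   would exceed this fraction of the 14-bit full scale (default 0.9).
#' @param drift `list(type = "none")` or `list(type = "ramp",
#'   amplitude = <ADU, up to ~100>, duration = <frames>)`.
#' @param scene `list(background = <photons/pixel/frame>, spots =
#'   data.frame(row, col, sigma, intensity))`; spot intensity is the
#'   expected photon total per frame in the spot.  The background may be a
#'   matrix of per-pixel rates (e.g. a radially falling diffuse-scattering
#'   profile with a water ring).
#' @param frame_time Seconds per frame.
#' @param rotation_speed Degrees per second.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return An object of class `jf_sim_config` with the true calibration in
#'   `$calibration`.
#' @export
sim_config <- function(dims = module_dims(),
                       beam_energy = 12.4,
                       e_per_photon = 3500,
                       noise_e_rms = 83,
                       pedestal_adu = c(1000, 1000, 1000),
                       pedestal_spread = 50,
                       rms_adu = NULL,
                       gain_switch_frac = 0.9,
                       drift = list(type = "none"),
                       scene = list(background = 1, spots = NULL),
                       frame_time = 880e-6,
                       rotation_speed = 100,
                       seed = 1L) {
  stopifnot(beam_energy > 0, e_per_photon > 0, noise_e_rms >= 0)
  calib <- default_calibration(dims, pedestal_adu = pedestal_adu)
  if (pedestal_spread > 0) {
    off <- with_seed(derive_seed(seed, "pedestal"), {
      lapply(1:3, function(i)
        matrix(stats::runif(prod(dims), -pedestal_spread, pedestal_spread),
               dims[1], dims[2]))
    })
    calib$pedestal$g0 <- calib$pedestal$g0 + off[[1]]
    calib$pedestal$g1 <- calib$pedestal$g1 + off[[2]]
    calib$pedestal$g2 <- calib$pedestal$g2 + off[[3]]
  }
  adu_per_photon_g0 <- beam_energy / calib$gain$g0[1, 1]
  sigma_adu_g0 <- noise_e_rms / e_per_photon * adu_per_photon_g0
  if (is.null(rms_adu)) rms_adu <- sigma_adu_g0
  calib$rms_g0[] <- rms_adu
  structure(list(dims = as.integer(dims), beam_energy = beam_energy,
                 e_per_photon = e_per_photon, noise_e_rms = noise_e_rms,
                 gain_switch_frac = gain_switch_frac, drift = drift,
                 scene = scene, frame_time = frame_time,
                 rotation_speed = rotation_speed, seed = as.integer(seed),
                 calibration = calib,
                 adu_per_photon_g0 = adu_per_photon_g0,
                 sigma_adu_g0 = sigma_adu_g0),
            class = "jf_sim_config")
}

#' @export
print.jf_sim_config <- function(x, ...) {
  cat(sprintf("<jf_sim_config> %d x %d, %g keV, noise %g e- (%.2f ADU at G0), seed %d\n",
              x$dims[1], x$dims[2], x$beam_energy, x$noise_e_rms,
              x$sigma_adu_g0, x$seed))
  invisible(x)
}

drift_at <- function(cfg, frame_index) {
  d <- cfg$drift
  if (is.null(d) || d$type == "none") return(rep(0, length(frame_index)))
  if (d$type == "ramp")
    return(d$amplitude * pmin(frame_index / d$duration, 1))
  stop("unknown drift profile")
}

#' Simulate dark frames at a forced gain level
#'
#' ADU = pedestal + drift(t) + Gaussian electronic noise, rounded and
#' clamped to the 14-bit range, with the gain bits forced to the requested
#' level (low-gain pedestals are collected in dedicated runs with the
#' detector forced to G1/G2).  Deterministic under the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @param n_frames Number of frames.
#' @param gain Forced gain level.
#' @param start_frame Frame number of the first frame (drift is evaluated
#'   at absolute frame numbers).
#' @return List with `frames`, the true `pedestal` map for the gain, the
#'   per-frame `drift` (ADU), and `sigma_adu`.
#' @export
simulate_dark <- function(cfg, n_frames, gain = "G0", start_frame = 0L) {
  stopifnot(inherits(cfg, "jf_sim_config"), n_frames >= 1)
  gi <- match(gain, gain_levels())
  if (is.na(gi)) stop("unknown gain level")
  ped <- cfg$calibration$pedestal[[c("g0", "g1", "g2")[gi]]]
  gain_factor <- cfg$calibration$gain[[c("g0", "g1", "g2")[gi]]]
  sigma_adu <- cfg$noise_e_rms / cfg$e_per_photon * cfg$beam_energy /
    abs(gain_factor[1, 1])
  idx <- start_frame + seq_len(n_frames) - 1L
  dr <- drift_at(cfg, idx)
  d <- cfg$dims
  frames <- with_seed(derive_seed(cfg$seed, paste0("dark", gain, start_frame)), {
    lapply(seq_len(n_frames), function(i) {
      adu <- ped + dr[i] +
        matrix(stats::rnorm(prod(d), 0, sigma_adu), d[1], d[2])
      adu <- pmin(pmax(round(adu), 0), 16383)
      raw_frame(matrix(encode_word(gi, adu), d[1], d[2]),
                frame_number = idx[i])
    })
  })
  list(frames = frames, pedestal = ped, drift = dr, sigma_adu = sigma_adu)
}

# Expected photon map for one frame: background plus Gaussian spots whose
# centers rotate about the image center with the rotation angle.
scene_lambda <- function(cfg, frame_index) {
  d <- cfg$dims
  bg <- cfg$scene$background
  lam <- if (is.matrix(bg)) bg else matrix(bg, d[1], d[2])
  stopifnot(identical(dim(lam), d), all(lam >= 0))
  spots <- cfg$scene$spots
  if (is.null(spots) || nrow(spots) == 0) return(lam)
  ang <- frame_index * cfg$rotation_speed * cfg$frame_time * pi / 180
  ctr <- (d + 1) / 2
  for (s in seq_len(nrow(spots))) {
    v <- c(spots$row[s] - ctr[1], spots$col[s] - ctr[2])
    rv <- c(cos(ang) * v[1] - sin(ang) * v[2],
            sin(ang) * v[1] + cos(ang) * v[2]) + ctr
    sg <- spots$sigma[s]
    rr <- max(1, floor(rv[1] - 4 * sg)):min(d[1], ceiling(rv[1] + 4 * sg))
    cc <- max(1, floor(rv[2] - 4 * sg)):min(d[2], ceiling(rv[2] + 4 * sg))
    if (length(rr) == 0 || length(cc) == 0) next
    g <- outer(stats::dnorm(rr, rv[1], sg), stats::dnorm(cc, rv[2], sg))
    lam[rr, cc] <- lam[rr, cc] + spots$intensity[s] * g / max(sum(g), 1e-12)
  }
  lam
}

#' Simulate diffraction frames with automatic gain switching
#'
#' Per frame: Poisson photons from the rotating scene, charge in keV plus
#' Gaussian electronic noise, then readout at the lowest gain whose ADU
#' stays below the switching threshold -- G0 until near saturation, then
#' G1, then G2 (clamped at 14-bit full scale).
#'
#' @param cfg A [sim_config()].
#' @param n_frames Number of frames.
#' @param start_frame Frame number of the first frame.
#' @return List with `frames`, `truth` (list of true photon-count maps),
#'   `expected` (list of expectation maps), and per-frame `angles`.
#' @export
simulate_diffraction <- function(cfg, n_frames, start_frame = 0L) {
  stopifnot(inherits(cfg, "jf_sim_config"), n_frames >= 1)
  d <- cfg$dims
  cal <- cfg$calibration
  thr <- cfg$gain_switch_frac * 16383
  sigma_kev <- cfg$noise_e_rms / cfg$e_per_photon * cfg$beam_energy
  idx <- start_frame + seq_len(n_frames) - 1L
  dr <- drift_at(cfg, idx)
  truth <- expected <- vector("list", n_frames)
  frames <- with_seed(derive_seed(cfg$seed, paste0("beam", start_frame)), {
    lapply(seq_len(n_frames), function(i) {
      lam <- scene_lambda(cfg, idx[i])
      expected[[i]] <<- lam
      n_ph <- matrix(stats::rpois(prod(d), lam), d[1], d[2])
      truth[[i]] <<- n_ph
      e_kev <- n_ph * cfg$beam_energy +
        matrix(stats::rnorm(prod(d), 0, sigma_kev), d[1], d[2])
      adu0 <- cal$pedestal$g0 + dr[i] + e_kev / cal$gain$g0
      adu1 <- cal$pedestal$g1 + e_kev / cal$gain$g1
      adu2 <- cal$pedestal$g2 + e_kev / cal$gain$g2
      gi <- matrix(1L, d[1], d[2])
      gi[adu0 > thr] <- 2L
      gi[gi == 2L & adu1 > thr] <- 3L
      adu <- adu0
      adu[gi == 2L] <- adu1[gi == 2L]
      adu[gi == 3L] <- adu2[gi == 3L]
      adu <- pmin(pmax(round(adu), 0), 16383)
      raw_frame(matrix(encode_word(as.vector(gi), as.vector(adu)), d[1], d[2]),
                frame_number = idx[i])
    })
  })
  list(frames = frames, truth = truth, expected = expected,
       angles = vapply(idx, function(j) angular_metadata(cfg, j)$start,
                       numeric(1)))
}

#' Rotation metadata for a frame
#'
#' The angular step per image is `rotation_speed * frame_time` (100 deg/s
#' at 880 microseconds gives 0.088 deg); the start angle is
#' `frame_index * step`.
#'
#' @param cfg A [sim_config()].
#' @param frame_index Frame index (0-based).
#' @return List with `start` and `step`, in degrees.
#' @export
angular_metadata <- function(cfg, frame_index) {
  step <- cfg$rotation_speed * cfg$frame_time
  list(start = frame_index * step, step = step)
}
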