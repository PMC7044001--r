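#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end flow (simulate or read raw frames,
#' packet transport, pedestal estimation, conversion, geometry expansion,
#' summation, rounding, compression, HDF5 output) with validation up front.
#' Values are echoed into the output metadata.
#'
#' @param output Output HDF5 path.
#' @param seed Master seed; every stage derives its stream from it.
#' @param dims Frame dimensions.
#' @param n_dark Dark frames before the shutter opens (G0 pedestal source).
#' @param n_beam Illuminated frames.
#' @param n_gain_dark Dedicated dark frames for the G1/G2 pedestal runs.
#' @param scene,drift Passed to [sim_config()].
#' @param beam_energy Photon energy (keV).
#' @param summation Frames summed per output image.
#' @param round_multiple Rounding multiple m in photons.
#' @param negative_policy `"keep"`, `"zero"` or `"offset"`.
#' @param negative_offset Offset for the `"offset"` policy.
#' @param codec,block_size,images_per_dataset Output compression settings.
#' @param expand_geometry Expand inter-chip large pixels before summation.
#' @param chip Chip dimensions for the geometry map.
#' @param stream `list(enabled =, loss_rate =, reorder =, payload_pixels =)`
#'   for the packet transport stage.
#' @param keep_raw Keep the raw gain+ADU frames on disk (default off: raw
#'   data is poorly compressible and normally converted on the fly).
#' @param raw_path Where to put raw frames when `keep_raw = TRUE`.
#' @return Validated config list of class `jf_pipeline_config`.
#' @export
pipeline_config <- function(output,
                            seed = 1L,
                            dims = module_dims(),
                            n_dark = 40L,
                            n_beam = 100L,
                            n_gain_dark = 10L,
                            scene = list(background = 1, spots = NULL),
                            drift = list(type = "none"),
                            beam_energy = 12.4,
                            summation = 1L,
                            round_multiple = 1,
                            negative_policy = "zero",
                            negative_offset = 0,
                            codec = "bslz4",
                            block_size = NULL,
                            images_per_dataset = 1000L,
                            expand_geometry = FALSE,
                            chip = NULL,
                            stream = list(enabled = FALSE, loss_rate = 0,
                                          reorder = FALSE,
                                          payload_pixels = NULL),
                            keep_raw = FALSE,
                            raw_path = NULL) {
  codec <- match.arg(codec, JF_CODECS)
  negative_policy <- match.arg(negative_policy, c("keep", "zero", "offset"))
  stopifnot(n_dark >= 2, n_beam >= 1, summation >= 1, round_multiple > 0,
            beam_energy > 0)
  if (keep_raw && is.null(raw_path))
    raw_path <- paste0(tools::file_path_sans_ext(output), "_raw.bin")
  cfg <- as.list(environment())
  class(cfg) <- "jf_pipeline_config"
  cfg
}

#' Per-frame statistics and anomaly flags
#'
#' The minimal online feature analysis: photon total, maximum pixel,
#' saturated and negative counts, plus flags that can inform the beamline
#' operator of anomalies (empty frames, suspiciously strong reflections).
#'
#' @param frame A [photon_frame()] or [quantized_frame()].
#' @param empty_threshold Total (photons) below which the frame is flagged
#'   empty.
#' @param strong_threshold Max pixel (photons) above which the frame is
#'   flagged as suspiciously strong.
#' @return List with `total`, `max`, `n_saturated`, `n_negative`, `empty`,
#'   `strong`.
#' @export
frame_stats <- function(frame, empty_threshold = 1,
                        strong_threshold = 5000) {
  if (inherits(frame, "jf_quantized_frame")) {
    sat <- quantized_sentinels()$saturated
    n_sat <- sum(frame$k == sat, na.rm = TRUE)
    v <- frame$k * frame$m
    v[!is.na(frame$k) & frame$k == sat] <- NA_real_
  } else {
    stopifnot(inherits(frame, "jf_photon_frame"))
    n_sat <- 0L
    v <- frame$values
  }
  total <- sum(v, na.rm = TRUE)
  mx <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  list(total = total, max = mx, n_saturated = n_sat,
       n_negative = sum(v < 0, na.rm = TRUE),
       empty = total < empty_threshold,
       strong = !is.na(mx) && mx > strong_threshold)
}

stage_time <- function(timings, name, t0) {
  timings[[name]] <- as.numeric(proc.time()["elapsed"]) - t0
  timings
}

#' Run the end-to-end conversion pipeline
#'
#' Simulate (dark then illuminated frames), optionally packetize and
#' reassemble over a lossy link, estimate pedestals (G1/G2 from dedicated
#' runs, G0 from the pre-illumination frames selected by
#' [detect_beam_start()]), convert with drift tracking, optionally expand
#' geometry, sum, round, compress and write the Eiger-dialect HDF5 file.
#' The run is bit-reproducible for a fixed config.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Run report: frame counters, gain occupancy, achieved bits/pixel,
#'   stage timings, output path.
#' @export
run_convert <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "jf_pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  t0 <- as.numeric(proc.time()["elapsed"])

  scfg <- sim_config(dims = config$dims, beam_energy = config$beam_energy,
                     drift = config$drift, scene = config$scene,
                     seed = config$seed)

  ## dedicated low-gain pedestal runs + main acquisition
  dark_g1 <- simulate_dark(scfg, config$n_gain_dark, gain = "G1")
  dark_g2 <- simulate_dark(scfg, config$n_gain_dark, gain = "G2")
  dark <- simulate_dark(scfg, config$n_dark, gain = "G0")
  beam <- simulate_diffraction(scfg, config$n_beam,
                               start_frame = config$n_dark)
  frames <- c(dark$frames, beam$frames)
  timings <- stage_time(timings, "simulate", t0)

  if (isTRUE(config$stream$enabled)) {
    t0 <- as.numeric(proc.time()["elapsed"])
    pp <- config$stream$payload_pixels %||% 4096L
    packets <- packetize_frames(frames, payload_pixels = pp)
    packets <- simulate_link(packets,
                             loss_rate = config$stream$loss_rate %||% 0,
                             reorder = isTRUE(config$stream$reorder),
                             seed = derive_seed(config$seed, "link"))
    asm <- assemble_frames(packets)
    frames <- asm$frames
    stream_report <- asm$report
    timings <- stage_time(timings, "stream", t0)
  } else stream_report <- NULL

  if (isTRUE(config$keep_raw)) {
    ok <- !vapply(frames, function(f) anyNA(f$pixels), logical(1))
    write_raw_frames(frames[ok], config$raw_path)
  }

  ## calibration: measured pedestals, gain factors from the calibration input
  t0 <- as.numeric(proc.time()["elapsed"])
  est_g1 <- estimate_pedestal(dark_g1$frames, "G1")
  est_g2 <- estimate_pedestal(dark_g2$frames, "G2")
  probe_calib <- scfg$calibration
  beam_start <- detect_beam_start(frames, probe_calib,
                                  beam_energy = config$beam_energy)
  fn <- vapply(frames, function(f) f$frame_number, integer(1))
  pre <- frames[!is.na(beam_start) & fn < beam_start]
  if (length(pre) < 2) stop("not enough pre-illumination frames for the G0 pedestal")
  est_g0 <- estimate_pedestal(pre, "G0")
  calib <- calibration(
    pedestal = list(g0 = est_g0$pedestal, g1 = est_g1$pedestal,
                    g2 = est_g2$pedestal),
    rms_g0 = est_g0$rms,
    gain = scfg$calibration$gain)
  tracker <- pedestal_tracker(est_g0$pedestal, est_g0$rms)
  timings <- stage_time(timings, "pedestal", t0)

  ## conversion with drift tracking
  t0 <- as.numeric(proc.time()["elapsed"])
  illum <- frames[fn >= beam_start]
  step <- angular_metadata(scfg, 0L)$step
  n_g1 <- n_g2 <- 0L
  converted <- vector("list", length(illum))
  for (i in seq_along(illum)) {
    pf <- convert_frame(illum[[i]], calib, tracker = tracker,
                        unit = "photons", beam_energy = config$beam_energy,
                        angular_span = step)
    tracker <- attr(pf, "tracker")
    attr(pf, "tracker") <- NULL
    dec_gain <- decode_frame(illum[[i]])$gain
    n_g1 <- n_g1 + sum(dec_gain == 2L, na.rm = TRUE)
    n_g2 <- n_g2 + sum(dec_gain == 3L, na.rm = TRUE)
    converted[[i]] <- pf
  }
  timings <- stage_time(timings, "convert", t0)

  if (isTRUE(config$expand_geometry)) {
    t0 <- as.numeric(proc.time()["elapsed"])
    chip <- config$chip %||% (config$dims %/% c(2L, 4L))
    gmap <- build_module_map(config$dims, chip = chip)
    converted <- lapply(converted, expand_module, map = gmap)
    timings <- stage_time(timings, "geometry", t0)
  }

  t0 <- as.numeric(proc.time()["elapsed"])
  n_sum <- config$summation
  remainder <- length(converted) %% n_sum
  if (remainder > 0)
    converted <- converted[seq_len(length(converted) - remainder)]
  images <- if (n_sum > 1) sum_frames(converted, n_sum) else converted
  quantized <- lapply(images, quantize, m = config$round_multiple,
                      negative_policy = config$negative_policy,
                      offset = config$negative_offset)
  stats <- lapply(quantized, frame_stats)
  timings <- stage_time(timings, "reduce", t0)

  t0 <- as.numeric(proc.time()["elapsed"])
  meta <- list(beam_energy = config$beam_energy,
               frame_time = scfg$frame_time,
               count_time = scfg$frame_time * n_sum,
               seed = as.integer(config$seed),
               summation = as.integer(n_sum))
  write_stack(quantized, config$output, codec = config$codec,
              block_size = config$block_size,
              images_per_dataset = config$images_per_dataset,
              metadata = meta)
  timings <- stage_time(timings, "write", t0)

  n_px <- prod(dim(quantized[[1]]))
  payload <- sum(vapply(quantized, function(f) {
    length(compress_chunk(as.integer(t(f$k)), codec = config$codec,
                          block_size = config$block_size %||%
                            default_block_size(config$codec),
                          element_bits = 32L)$payload)
  }, numeric(1)))

  say("wrote %d images to %s", length(quantized), config$output)
  list(output = config$output,
       frames_in = length(frames),
       frames_dark = sum(fn < beam_start),
       frames_converted = length(illum),
       images_out = length(quantized),
       summation_remainder = remainder,
       beam_start = beam_start,
       n_g1_pixels = n_g1, n_g2_pixels = n_g2,
       bits_per_pixel = payload * 8 / (n_px * length(quantized)),
       empty_images = sum(vapply(stats, `[[`, logical(1), "empty")),
       strong_images = sum(vapply(stats, `[[`, logical(1), "strong")),
       stream = stream_report,
       timings = timings)
}
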