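#' Split a raw frame into a synthetic datagram stream
#'
#' Models the detector's UDP sender: the frame's pixel words, in row-major
#' order, are cut into fixed-size payloads.  The packet schema (magic,
#' module id, frame number, packet index, packets per frame) is
#' self-defined and versioned; the real detector packet layout is not
#' modeled.
#'
#' @param frame A [raw_frame()].
#' @param payload_pixels Pixels per packet; must divide the pixel count.
#'   The default 4096 pixels (8192 bytes) gives 128 packets per module
#'   frame.
#' @return List of packets (class `jf_packet`).
#' @export
packetize_frame <- function(frame, payload_pixels = 4096L) {
  stopifnot(inherits(frame, "jf_raw_frame"))
  n <- length(frame$pixels)
  if (n %% payload_pixels != 0)
    stop("payload_pixels must divide the pixel count")
  if (anyNA(frame$pixels)) stop("cannot packetize a frame with missing pixels")
  words <- as.integer(t(frame$pixels))
  ppf <- n %/% payload_pixels
  dims <- dim(frame$pixels)
  lapply(seq_len(ppf) - 1L, function(i) {
    structure(list(module_id = frame$module_id,
                   frame_number = frame$frame_number,
                   packet_index = i,
                   packets_per_frame = ppf,
                   dims = dims,
                   payload = words[(i * payload_pixels + 1L):((i + 1L) * payload_pixels)]),
              class = "jf_packet")
  })
}

#' Packetize a sequence of frames
#'
#' @param frames List of [raw_frame()] objects.
#' @param payload_pixels Pixels per packet.
#' @return Flat list of packets in emission order.
#' @export
packetize_frames <- function(frames, payload_pixels = 4096L) {
  do.call(c, lapply(frames, packetize_frame, payload_pixels = payload_pixels))
}

#' Simulate a lossy, reordering network link
#'
#' Each packet is independently dropped with probability `loss_rate`
#' (receiver-buffer overflow on a UDP link loses packets irrecoverably);
#' optional bounded reordering jitters packet positions by up to `window`
#' slots.  Deterministic under `seed`.
#'
#' @param packets List of packets.
#' @param loss_rate Drop probability in `[0, 1)`.
#' @param reorder Apply bounded reordering.
#' @param window Maximum displacement, in packets, under reordering.
#' @param seed Integer seed (the caller's RNG state is left untouched).
#' @return The surviving packets in arrival order.
#' @export
simulate_link <- function(packets, loss_rate = 0, reorder = FALSE,
                          window = 32L, seed = NULL) {
  stopifnot(loss_rate >= 0, loss_rate < 1)
  with_seed(seed, {
    keep <- if (loss_rate > 0) stats::runif(length(packets)) >= loss_rate
            else rep(TRUE, length(packets))
    out <- packets[keep]
    if (reorder && length(out) > 1)
      out <- out[order(seq_along(out) + stats::runif(length(out), 0, window))]
    out
  })
}

#' Reassemble frames from a packet stream
#'
#' Packets may arrive out of order; at most `window` frames are kept in
#' flight (the real-time constraint modeled as a bounded reorder window).
#' When the window is full, the oldest frame is flushed: if packets are
#' missing its pixel regions are masked (`NA` words) and the frame is
#' counted incomplete.  Packets for frames already flushed are counted as
#' late-lost; conflicting duplicates keep the first copy.
#'
#' @param packets List of packets.
#' @param window Maximum frames in flight.
#' @return List with `frames` (by ascending frame number, masks as `NA`
#'   pixels) and `report`: `frames_complete`, `frames_incomplete`,
#'   `packets_lost`, `packets_late`, `duplicates`, `missing` (named list of
#'   missing 0-based packet indices per incomplete frame), and
#'   `missing_frames` (frame numbers inside the observed range never seen
#'   at all, included in `packets_lost`).
#' @export
assemble_frames <- function(packets, window = 16L) {
  buf <- new.env(parent = emptyenv())
  order_seen <- character(0)
  flushed <- character(0)
  out <- list()
  missing <- list()
  complete <- incomplete <- lost <- late <- dup <- 0L

  flush_one <- function(key) {
    e <- get(key, envir = buf)
    got <- !vapply(e$slots, is.null, logical(1))
    words <- unlist(lapply(seq_along(e$slots), function(i) {
      if (got[i]) e$slots[[i]] else rep(NA_integer_, e$payload_n)
    }), use.names = FALSE)
    fr <- raw_frame(matrix(words, nrow = e$dims[1], ncol = e$dims[2],
                           byrow = TRUE),
                    module_id = e$module_id, frame_number = e$frame_number)
    if (all(got)) complete <<- complete + 1L
    else {
      incomplete <<- incomplete + 1L
      lost <<- lost + sum(!got) # nolint
      missing[[as.character(e$frame_number)]] <<- which(!got) - 1L
    }
    out[[length(out) + 1L]] <<- fr
    rm(list = key, envir = buf)
    flushed <<- c(flushed, key)
    order_seen <<- setdiff(order_seen, key)
  }

  for (p in packets) {
    key <- sprintf("%d.%d", p$module_id, p$frame_number)
    if (key %in% flushed) { late <- late + 1L; next }
    if (!exists(key, envir = buf)) {
      if (length(order_seen) >= window) flush_one(order_seen[1])
      assign(key, list(module_id = p$module_id,
                       frame_number = p$frame_number,
                       dims = p$dims,
                       payload_n = length(p$payload),
                       slots = vector("list", p$packets_per_frame)),
             envir = buf)
      order_seen <- c(order_seen, key)
    }
    e <- get(key, envir = buf)
    slot <- p$packet_index + 1L
    if (!is.null(e$slots[[slot]])) { dup <- dup + 1L; next }
    e$slots[[slot]] <- p$payload
    assign(key, e, envir = buf)
  }
  while (length(order_seen) > 0) flush_one(order_seen[1])

  fn <- vapply(out, function(f) f$frame_number, integer(1))
  out <- out[order(fn)]
  missing_frames <- integer(0)
  if (length(fn) > 0) {
    rng <- min(fn):max(fn)
    missing_frames <- setdiff(rng, fn)
    if (length(missing_frames) > 0 && length(out) > 0) {
      ppf <- packets[[1]]$packets_per_frame
      lost <- lost + length(missing_frames) * ppf
    }
  }
  list(frames = out,
       report = list(frames_complete = complete,
                     frames_incomplete = incomplete,
                     packets_lost = lost + late,
                     packets_late = late,
                     duplicates = dup,
                     missing = missing,
                     missing_frames = missing_frames))
}

STREAM_MAGIC <- charToRaw("JFPK")

#' Write a packet stream to a binary file
#'
#' Fixed-size little-endian headers (magic, module id, frame number, packet
#' index, packets per frame, frame rows/cols, payload pixel count) followed
#' by the 16-bit payload words.
#'
#' @param packets List of packets.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_packet_stream <- function(packets, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in packets) {
    writeBin(STREAM_MAGIC, con)
    writeBin(as.integer(c(p$module_id, p$frame_number, p$packet_index,
                          p$packets_per_frame, p$dims[1], p$dims[2],
                          length(p$payload))),
             con, size = 4, endian = "little")
    writeBin(.Call(C_pack_u16, p$payload), con)
  }
  invisible(path)
}

#' Read a packet stream from a binary file
#'
#' @param path File written by [write_packet_stream()].
#' @return List of packets.
#' @export
read_packet_stream <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  packets <- list()
  repeat {
    magic <- readBin(con, "raw", 4)
    if (length(magic) == 0) break
    if (!identical(magic, STREAM_MAGIC)) stop("bad magic in packet stream")
    hdr <- readBin(con, "integer", 7, size = 4, endian = "little")
    bytes <- readBin(con, "raw", 2 * hdr[7])
    packets[[length(packets) + 1L]] <-
      structure(list(module_id = hdr[1], frame_number = hdr[2],
                     packet_index = hdr[3], packets_per_frame = hdr[4],
                     dims = hdr[5:6], payload = .Call(C_unpack_u16, bytes)),
                class = "jf_packet")
  }
  packets
}
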