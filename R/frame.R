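#' Module dimensions of the detector
#'
#' A single detector module has 524 288 pixels organized into 1024 columns
#' and 512 rows, read out as 16-bit words over its own network links.
#'
#' @return Integer vector `c(rows, columns)` = `c(512L, 1024L)`.
#' @export
module_dims <- function() c(512L, 1024L)

#' Raw module frame
#'
#' One module readout: a matrix of 16-bit pixel words (2-bit gain code plus
#' 14-bit ADU), a frame number and a module id.  Desk-scale work may use
#' smaller matrices; file and stream I/O record the dimensions explicitly.
#'
#' @param pixels Integer matrix of pixel words in `[0, 65535]`.  `NA`
#'   entries mark pixels lost in transport (see [assemble_frames()]).
#' @param module_id Integer module identifier.
#' @param frame_number Integer frame number (>= 0).
#' @return An object of class `jf_raw_frame`.
#' @export
raw_frame <- function(pixels, module_id = 0L, frame_number = 0L) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "integer"
  bad <- pixels[!is.na(pixels)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 65535L))
    stop("pixel words must be 16-bit unsigned integers")
  structure(
    list(pixels = pixels,
         module_id = as.integer(module_id),
         frame_number = as.integer(frame_number)),
    class = "jf_raw_frame"
  )
}

#' @export
print.jf_raw_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<jf_raw_frame> module %d, frame %d, %d x %d pixels\n",
              x$module_id, x$frame_number, d[1], d[2]))
  n_na <- sum(is.na(x$pixels))
  if (n_na > 0) cat(sprintf("  %d pixels missing (lost packets)\n", n_na))
  invisible(x)
}

#' @export
dim.jf_raw_frame <- function(x) dim(x$pixels)

RAW_FILE_MAGIC <- charToRaw("JFRW")
RAW_FILE_VERSION <- 1L

#' Write raw module frames to a binary file
#'
#' On-disk dialect: per frame a 32-byte header (4-byte magic `"JFRW"`,
#' then little-endian uint32 version, module id, frame number, rows,
#' columns, and 8 reserved bytes) followed by the pixel words as
#' little-endian 16-bit values in row-major order.
#'
#' @param frames A `jf_raw_frame` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raw_frames <- function(frames, path) {
  if (inherits(frames, "jf_raw_frame")) frames <- list(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in frames) {
    stopifnot(inherits(f, "jf_raw_frame"))
    if (anyNA(f$pixels))
      stop("cannot serialize a frame with missing pixels")
    d <- dim(f$pixels)
    writeBin(RAW_FILE_MAGIC, con)
    writeBin(as.integer(c(RAW_FILE_VERSION, f$module_id, f$frame_number,
                          d[1], d[2])), con, size = 4, endian = "little")
    writeBin(raw(8), con)
    writeBin(.Call(C_pack_u16, as.integer(t(f$pixels))), con)
  }
  invisible(path)
}

#' Read raw module frames from a binary file
#'
#' @param path File written by [write_raw_frames()].
#' @return List of `jf_raw_frame` objects.
#' @export
read_raw_frames <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- list()
  repeat {
    magic <- readBin(con, "raw", 4)
    if (length(magic) == 0) break
    if (!identical(magic, RAW_FILE_MAGIC)) stop("bad magic in raw frame file")
    hdr <- readBin(con, "integer", 5, size = 4, endian = "little")
    readBin(con, "raw", 8)
    if (hdr[1] != RAW_FILE_VERSION) stop("unsupported raw file version")
    nr <- hdr[4]; nc <- hdr[5]
    bytes <- readBin(con, "raw", 2 * nr * nc)
    if (length(bytes) != 2 * nr * nc) stop("truncated raw frame file")
    words <- .Call(C_unpack_u16, bytes)
    frames[[length(frames) + 1L]] <-
      raw_frame(matrix(words, nrow = nr, ncol = nc, byrow = TRUE),
                module_id = hdr[2], frame_number = hdr[3])
  }
  frames
}
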