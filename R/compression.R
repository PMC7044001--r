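#' Bitshuffle: block bit-plane transposition
#'
#' Reorders the bits of a vector of fixed-width integers so that bits of
#' equal significance are stored together: with the canonical `"msb"`
#' order, the highest bits of all numbers come first, then the
#' second-highest, and so on.  Diffraction images are mostly low counts of
#' similar magnitude, so after the transform most of the output is long
#' zero runs, which dictionary compressors exploit.  The `"filter"` order
#' is the byte-lane-grouped layout used inside the HDF5 bitshuffle filter
#' stream (little-endian byte lanes, most significant bit first within each
#' lane); it is the order used by [compress_chunk()] for the `bslz4` and
#' `bszstd` codecs so written chunks match the filter convention.
#'
#' @param bytes Raw vector of little-endian elements.
#' @param element_size Element width in bytes: 2, 4 or 8.
#' @param order `"msb"` (canonical) or `"filter"`.
#' @return Raw vector of the same length; element count must be a multiple
#'   of 8.
#' @export
bitshuffle <- function(bytes, element_size = 2L, order = c("msb", "filter")) {
  order <- match.arg(order)
  .Call(C_bitshuffle, bytes, as.integer(element_size),
        if (order == "msb") 0L else 1L)
}

#' Inverse of [bitshuffle()]
#'
#' @inheritParams bitshuffle
#' @return Raw vector with the original element order restored.
#' @export
bitunshuffle <- function(bytes, element_size = 2L, order = c("msb", "filter")) {
  order <- match.arg(order)
  .Call(C_bitunshuffle, bytes, as.integer(element_size),
        if (order == "msb") 0L else 1L)
}

#' Pack integer pixel values into little-endian bytes
#'
#' @param values Integer vector; 16-bit packing requires `[0, 65535]`,
#'   32-bit packing accepts any R integer (`NA` keeps its -2^31 bit
#'   pattern, the masked sentinel).
#' @param element_bits 16 or 32.
#' @return Raw vector.
#' @export
pack_values <- function(values, element_bits = 16L) {
  if (element_bits == 16L) return(.Call(C_pack_u16, as.integer(values)))
  if (element_bits == 32L) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    v <- as.integer(values)
    v[is.na(v)] <- NA_integer_
    writeBin(v, con, size = 4, endian = "little")
    return(rawConnectionValue(con))
  }
  if (element_bits == 64L) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    writeBin(as.double(values), con, size = 8, endian = "little")
    return(rawConnectionValue(con))
  }
  stop("element_bits must be 16, 32 or 64")
}

#' Unpack little-endian bytes into values
#'
#' @param bytes Raw vector.
#' @param element_bits 16, 32 or 64.
#' @return Integer vector (16/32) or double vector (64).
#' @export
unpack_values <- function(bytes, element_bits = 16L) {
  if (element_bits == 16L) return(.Call(C_unpack_u16, bytes))
  n <- length(bytes) %/% (element_bits %/% 8L)
  if (element_bits == 32L)
    return(readBin(bytes, "integer", n, size = 4, endian = "little"))
  if (element_bits == 64L)
    return(readBin(bytes, "double", n, size = 8, endian = "little"))
  stop("element_bits must be 16, 32 or 64")
}

JF_CODECS <- c("none", "gzip", "lz4", "zstd", "bslz4", "bszstd")

default_block_size <- function(codec) {
  # 8 kB blocks fit CPU cache for Bitshuffle/LZ4; Bitshuffle/Zstd profits
  # from longer 64 kB blocks
  if (codec == "bszstd") 65536 else 8192
}

#' Compress a chunk of pixel values
#'
#' Lossless chunk compression as used for detector frames: the two-step
#' `bslz4`/`bszstd` codecs bitshuffle each block (8 kB default; 64 kB for
#' `bszstd`) before the dictionary stage and use the HDF5 bitshuffle-filter
#' stream framing (8-byte big-endian element count, 4-byte big-endian block
#' size, then per-block length-prefixed compressed blocks), so chunks are
#' readable by standard filter implementations.  Plain `lz4` uses the same
#' framing without the shuffle, `zstd` is a raw Zstandard frame, `gzip` a
#' zlib stream, and `none` stores the bytes verbatim.
#'
#' @param values Integer vector (or raw bytes) to compress.
#' @param codec One of `r paste0('"', JF_CODECS, '"', collapse = ", ")`.
#' @param block_size Bitshuffle block size in bytes.
#' @param element_bits Element width of `values` (16 or 32; 64 for doubles).
#' @param level Compression level for zstd/gzip backends.
#' @return An object of class `jf_chunk`.
#' @export
compress_chunk <- function(values, codec = "bslz4", block_size = NULL,
                           element_bits = 16L, level = 3L) {
  codec <- match.arg(codec, JF_CODECS)
  if (is.null(block_size)) block_size <- default_block_size(codec)
  bytes <- if (is.raw(values)) values else pack_values(values, element_bits)
  esize <- as.integer(element_bits %/% 8L)
  n_elements <- length(bytes) %/% esize
  payload <- switch(codec,
    none = bytes,
    gzip = .Call(C_zlib_compress, bytes, as.integer(level)),
    lz4 = .Call(C_bshuf_compress, bytes, esize, as.double(block_size),
                2L, 0L, as.integer(level)),
    zstd = .Call(C_zstd_compress, bytes, as.integer(level)),
    bslz4 = .Call(C_bshuf_compress, bytes, esize, as.double(block_size),
                  2L, 1L, as.integer(level)),
    bszstd = .Call(C_bshuf_compress, bytes, esize, as.double(block_size),
                   5L, 1L, as.integer(level))
  )
  structure(list(codec = codec, block_size = block_size,
                 n_elements = n_elements, element_bits = as.integer(element_bits),
                 payload = payload),
            class = "jf_chunk")
}

#' @export
print.jf_chunk <- function(x, ...) {
  cat(sprintf("<jf_chunk> %s, %d x %d-bit elements, %d bytes (%.3f bits/pixel)\n",
              x$codec, x$n_elements, x$element_bits, length(x$payload),
              bits_per_pixel(x, x$n_elements)))
  invisible(x)
}

#' Decompress a chunk
#'
#' @param chunk A [compress_chunk()] result.
#' @param as_raw Return raw bytes instead of unpacked values.
#' @return The original values (or bytes).
#' @export
decompress_chunk <- function(chunk, as_raw = FALSE) {
  stopifnot(inherits(chunk, "jf_chunk"))
  esize <- chunk$element_bits %/% 8L
  n_bytes <- chunk$n_elements * esize
  bytes <- switch(chunk$codec,
    none = chunk$payload,
    gzip = .Call(C_zlib_decompress, chunk$payload, as.double(n_bytes)),
    lz4 = .Call(C_bshuf_decompress, chunk$payload,
                as.integer(c(esize, 0L, 2L))),
    zstd = .Call(C_zstd_decompress, chunk$payload),
    bslz4 = .Call(C_bshuf_decompress, chunk$payload,
                  as.integer(c(esize, 1L, 2L))),
    bszstd = .Call(C_bshuf_decompress, chunk$payload,
                   as.integer(c(esize, 1L, 5L))),
    stop("unknown codec: ", chunk$codec)
  )
  if (length(bytes) != n_bytes) stop("decompressed size mismatch")
  if (as_raw) bytes else unpack_values(bytes, chunk$element_bits)
}

#' Compressed size in bits per pixel
#'
#' Total payload bytes times 8, divided by the pixel count; 16-bit raw data
#' stored uncompressed is exactly 16.0.
#'
#' @param chunks A `jf_chunk` or list of them.
#' @param n_pixels Total number of pixels represented.
#' @return Bits per pixel (double).
#' @export
bits_per_pixel <- function(chunks, n_pixels) {
  stopifnot(n_pixels > 0)
  if (inherits(chunks, "jf_chunk")) chunks <- list(chunks)
  total <- sum(vapply(chunks, function(ch) length(ch$payload), numeric(1)))
  total * 8 / n_pixels
}

#' Error-bounded lossy compression of a converted frame
#'
#' A precision-guaranteed codec in the spirit of lossy compressors for
#' scientific arrays: each detector row is predicted by the previous
#' reconstructed value, residuals are quantized with step `2 * e` (so the
#' reconstruction is always within the absolute error bound `e`), row
#' starts and irregular pixels are stored verbatim as escapes, and the
#' quantized residuals go through Bitshuffle/Zstd.  Deterministic;
#' masked (`NA`) pixels survive the round trip.
#'
#' @param frame A [photon_frame()] (or numeric matrix).
#' @param e Absolute error bound in photons (> 0).
#' @param level Zstd level for the entropy stage.
#' @return A `jf_chunk` with codec `"lossy_abs"`.
#' @export
lossy_compress <- function(frame, e, level = 3L) {
  if (inherits(frame, "jf_photon_frame")) {
    v <- frame$values
    unit <- frame$unit
    span <- frame$angular_span
  } else {
    v <- frame
    unit <- "photons"
    span <- NA_real_
  }
  stopifnot(is.matrix(v))
  if (!is.numeric(e) || length(e) != 1 || e <= 0)
    stop("error bound e must be positive")
  enc <- .Call(C_lossy_encode, as.double(v), nrow(v), ncol(v), as.double(e))
  codes_comp <- .Call(C_bshuf_compress, pack_values(enc$codes, 32L), 4L,
                      8192, 5L, 1L, as.integer(level))
  esc_bytes <- pack_values(enc$escapes, 64L)
  header <- pack_values(c(length(enc$escapes), length(codes_comp)), 32L)
  structure(list(codec = "lossy_abs", block_size = 8192,
                 n_elements = length(v), element_bits = 64L,
                 error_bound = e, dims = dim(v), unit = unit,
                 angular_span = span,
                 payload = c(header, codes_comp, esc_bytes)),
            class = "jf_chunk")
}

#' Decompress an error-bounded lossy chunk
#'
#' @param chunk A chunk from [lossy_compress()].
#' @return A [photon_frame()] satisfying `max(abs(x_hat - x)) <= e`.
#' @export
lossy_decompress <- function(chunk) {
  stopifnot(inherits(chunk, "jf_chunk"), chunk$codec == "lossy_abs")
  hdr <- unpack_values(chunk$payload[1:8], 32L)
  n_esc <- hdr[1]; n_codes_comp <- hdr[2]
  codes_comp <- chunk$payload[8 + seq_len(n_codes_comp)]
  esc_bytes <- chunk$payload[(8 + n_codes_comp + 1):length(chunk$payload)]
  codes <- unpack_values(.Call(C_bshuf_decompress, codes_comp,
                               as.integer(c(4L, 1L, 5L))), 32L)
  escapes <- unpack_values(esc_bytes, 64L)[seq_len(n_esc)]
  v <- .Call(C_lossy_decode, codes, as.double(escapes),
             chunk$dims[1], chunk$dims[2], chunk$error_bound)
  photon_frame(v, unit = chunk$unit, mask = is.na(v) | is.nan(v),
               angular_span = chunk$angular_span)
}
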