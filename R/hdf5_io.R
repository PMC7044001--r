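#' Write converted frames as an Eiger-dialect HDF5 stack
#'
#' Frames go to `/entry/data/data_000001`, `data_000002`, ... with
#' `images_per_dataset` images each, chunked one frame per chunk
#' (`1 x H x W`) and annotated with `image_nr_low`/`image_nr_high`
#' attributes.  Chunks are compressed by the compression module and handed
#' to the HDF5 library pre-compressed through its direct chunk writer; the
#' filter pipeline entry (bitshuffle filter id 32008, LZ4 32004, Zstd
#' 32015, deflate 1) is recorded so any reader with the matching filter
#' plugin decodes the data.  Provenance the NXmx standard cannot express --
#' the rounding multiple, negative-count policy, calibration checksum and
#' simulator seed -- is stored as attributes under `/entry/jfproc`.
#'
#' @param frames List of [quantized_frame()] objects (stored as int32 with
#'   sentinel codes) or [photon_frame()] objects (stored as float64, masked
#'   pixels as NaN).
#' @param path Output HDF5 file.
#' @param codec Chunk codec (see [compress_chunk()]).
#' @param block_size Bitshuffle block size in bytes (default per codec).
#' @param images_per_dataset Images per dataset, default 1000.
#' @param metadata Named list of scalar provenance attributes (numbers or
#'   strings), e.g. `beam_energy`, `frame_time`, `count_time`, `seed`,
#'   `calibration_sha1`.
#' @param level Compression level for zstd/gzip.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, codec = "bslz4", block_size = NULL,
                        images_per_dataset = 1000L, metadata = list(),
                        level = 3L) {
  stopifnot(length(frames) >= 1)
  codec <- match.arg(codec, JF_CODECS)
  if (is.null(block_size)) block_size <- default_block_size(codec)
  quantized <- inherits(frames[[1]], "jf_quantized_frame")
  if (!quantized && !inherits(frames[[1]], "jf_photon_frame"))
    stop("frames must be quantized or photon frames")
  d <- dim(frames[[1]])
  element_bits <- if (quantized) 32L else 64L

  chunks <- lapply(frames, function(f) {
    if (!identical(class(f), class(frames[[1]])) || !identical(dim(f), d))
      stop("frames are not homogeneous in shape and type")
    vals <- if (quantized) as.integer(t(f$k)) else {
      v <- f$values
      v[f$mask] <- NaN
      as.double(t(v))
    }
    compress_chunk(vals, codec = codec, block_size = block_size,
                   element_bits = element_bits, level = level)$payload
  })

  meta <- metadata
  meta$software <- paste0("jfproc ",
                          as.character(utils::packageVersion("jfproc")))
  if (quantized) {
    meta$round_multiple <- frames[[1]]$m
    meta$negative_policy <- frames[[1]]$negative_policy
  }
  meta$unit <- if (quantized) "photons" else frames[[1]]$unit
  spans <- vapply(frames, function(f) f$angular_span %||% NA_real_, numeric(1))
  if (!all(is.na(spans))) meta$angular_span_per_image <- spans[1]
  meta$codec <- codec
  meta$block_size <- as.integer(block_size)

  esize <- element_bits %/% 8L
  filter_info <- switch(codec,
    none = list(0L, integer(0)),
    gzip = list(1L, as.integer(level)),
    lz4 = list(32004L, as.integer(c(block_size, esize))),
    zstd = list(32015L, as.integer(level)),
    bslz4 = list(32008L, as.integer(c(0, 4, esize, block_size %/% esize, 2))),
    bszstd = list(32008L, as.integer(c(0, 4, esize, block_size %/% esize, 5)))
  )
  .Call(C_h5_write_stack, path.expand(path), chunks, as.integer(d),
        if (quantized) "int32" else "double", as.integer(images_per_dataset),
        filter_info, meta)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

decode_stack_chunk <- function(bytes, filter_id, cd, n_bytes, element_bits) {
  esize <- element_bits %/% 8L
  if (filter_id == 0L) bytes
  else if (filter_id == 1L) .Call(C_zlib_decompress, bytes, as.double(n_bytes))
  else if (filter_id == 32004L)
    .Call(C_bshuf_decompress, bytes, as.integer(c(esize, 0L, 2L)))
  else if (filter_id == 32015L) .Call(C_zstd_decompress, bytes)
  else if (filter_id == 32008L) {
    codec <- if (length(cd) >= 5) cd[5] else 2L
    .Call(C_bshuf_decompress, bytes, as.integer(c(cd[3], 1L, codec)))
  } else stop("unsupported HDF5 filter id: ", filter_id)
}

#' Read an HDF5 image stack written by [write_stack()]
#'
#' Chunks are read raw through the direct chunk reader and decompressed by
#' the compression module; an unknown filter id raises an explicit error.
#'
#' @param path HDF5 file.
#' @return List with `frames` (quantized or photon frames, reconstructed
#'   with sentinels/masks) and `metadata` (the `/entry/jfproc` attributes).
#' @export
read_stack <- function(path) {
  st <- .Call(C_h5_read_stack, path.expand(path))
  H <- st$dims[1]; W <- st$dims[2]
  quantized <- st$dtype == "int32"
  element_bits <- if (quantized) 32L else 64L
  n_bytes <- H * W * (element_bits %/% 8L)
  meta <- st$attrs
  m <- meta$round_multiple %||% 1
  npol <- meta$negative_policy %||% "keep"
  span <- meta$angular_span_per_image %||% NA_real_

  frames <- list()
  for (dsname in sort(names(st$datasets))) {
    ds <- st$datasets[[dsname]]
    for (ch in ds$chunks) {
      bytes <- decode_stack_chunk(ch, ds$filter_id, ds$cd_values,
                                  n_bytes, element_bits)
      vals <- unpack_values(bytes, element_bits)
      frames[[length(frames) + 1L]] <- if (quantized) {
        quantized_frame(matrix(vals, H, W, byrow = TRUE), m = m,
                        angular_span = span, negative_policy = npol)
      } else {
        v <- matrix(vals, H, W, byrow = TRUE)
        mask <- !is.finite(v)
        v[mask] <- NA_real_
        photon_frame(v, unit = meta$unit %||% "photons", mask = mask,
                     angular_span = span)
      }
    }
  }
  list(frames = frames, metadata = meta)
}

#' Read a dataset through the regular HDF5 filtered read path
#'
#' Cross-check helper: instead of the direct chunk reader this goes through
#' `H5Dread`, so decompression is performed by the HDF5 filter pipeline
#' (the library's own deflate for gzip; the registered filter callbacks for
#' bitshuffle/LZ4/Zstd ids).
#'
#' @param path HDF5 file.
#' @param dataset Dataset path, e.g. `"/entry/data/data_000001"`.
#' @return Array of the dataset contents (images, rows, cols).
#' @export
read_stack_filtered <- function(path, dataset = "/entry/data/data_000001") {
  v <- .Call(C_h5_read_dataset_filtered, path.expand(path), dataset)
  d <- attr(v, "h5dims")
  # HDF5 row-major (n, H, W) -> R array
  aperm(array(v, dim = rev(d)), length(d):1)
}
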