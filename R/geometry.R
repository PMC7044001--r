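#' Build the large-pixel expansion map for a module
#'
#' A module is built from a grid of readout chips (4 columns x 2 rows of
#' 256 x 256 pixels in the standard construction).  Sensor pixels adjacent
#' to an internal chip boundary are physically double width (or height);
#' pixels at internal chip corners are double in both directions.  To make
#' all output pixels equal-sized, boundary pixels are split into 2 output
#' pixels and corner pixels into 4, giving 514 x 1030 output pixels for a
#' 512 x 1024 module.  The expansion is separable: each axis maps source
#' indices to output indices with weights, and the weights of all output
#' pixels fed by one source pixel sum to 1 when intensity is divided.
#'
#' @param dims Module dimensions `c(rows, cols)`.
#' @param chip Chip dimensions `c(rows, cols)`; both must divide `dims`.
#' @param divide If `TRUE` (default) a split pixel's intensity is divided
#'   equally (weights 1/2 or 1/4), conserving integrated Bragg
#'   intensities; if `FALSE` the value is replicated (weights 1), the
#'   convention some integration programs expect.
#' @return An object of class `jf_geometry_map`.
#' @export
build_module_map <- function(dims = module_dims(), chip = c(256L, 256L),
                             divide = TRUE) {
  stopifnot(dims %% chip == 0)
  axis_map <- function(n, chip_n) {
    n_chips <- n %/% chip_n
    # pixels on both sides of each internal boundary are large
    big <- as.vector(vapply(seq_len(n_chips - 1),
                            function(b) c(b * chip_n, b * chip_n + 1L),
                            integer(2)))
    src <- integer(0)
    w <- numeric(0)
    for (i in seq_len(n)) {
      rep_i <- if (i %in% big) 2L else 1L
      src <- c(src, rep(i, rep_i))
      w <- c(w, rep(if (divide) 1 / rep_i else 1, rep_i))
    }
    list(src = src, w = w)
  }
  rmap <- axis_map(dims[1], chip[1])
  cmap <- axis_map(dims[2], chip[2])
  structure(list(row_src = rmap$src, row_w = rmap$w,
                 col_src = cmap$src, col_w = cmap$w,
                 dims_in = as.integer(dims),
                 dims_out = c(length(rmap$src), length(cmap$src)),
                 chip = as.integer(chip), divide = divide),
            class = "jf_geometry_map")
}

#' @export
print.jf_geometry_map <- function(x, ...) {
  cat(sprintf("<jf_geometry_map> %d x %d -> %d x %d (%s)\n",
              x$dims_in[1], x$dims_in[2], x$dims_out[1], x$dims_out[2],
              if (x$divide) "intensity divided" else "value replicated"))
  invisible(x)
}

#' Count of source pixels by number of output pixels
#'
#' @param map A [build_module_map()].
#' @return Named integer vector: sources feeding 1, 2 and 4 output pixels.
#' @export
pixel_split_counts <- function(map) {
  rr <- tabulate(map$row_src, nbins = map$dims_in[1])
  cc <- tabulate(map$col_src, nbins = map$dims_in[2])
  n <- outer(rr, cc)
  c(single = sum(n == 1), double = sum(n == 2), quad = sum(n == 4))
}

#' Expand the oversized inter-chip pixels of a converted frame
#'
#' @param frame A [photon_frame()] in unexpanded module shape.
#' @param map A [build_module_map()] matching the frame.
#' @return The expanded [photon_frame()].
#' @export
expand_module <- function(frame, map) {
  stopifnot(inherits(frame, "jf_photon_frame"),
            inherits(map, "jf_geometry_map"))
  if (frame$expanded)
    stop("frame is already expanded")
  if (!identical(dim(frame$values), map$dims_in))
    stop("frame shape does not match the geometry map")
  w <- outer(map$row_w, map$col_w)
  v <- frame$values[map$row_src, map$col_src] * w
  mask <- frame$mask[map$row_src, map$col_src]
  v[mask] <- NA_real_
  photon_frame(v, unit = frame$unit, mask = mask,
               angular_span = frame$angular_span, expanded = TRUE)
}

#' Default multi-module detector layout
#'
#' Modules are placed on a two-column grid (the 4 Mpixel class detector is
#' 8 modules) with masked mechanical gaps between them.  Gap sizes are
#' configurable; they are masks, not metrology.
#'
#' @param module_ids Integer vector of module ids.
#' @param module_dims Expanded module dimensions, default `c(514, 1030)`.
#' @param gap `c(rows, cols)` of masked pixels between adjacent modules.
#' @param ncol_modules Number of module columns in the layout.
#' @return Data frame with `module_id`, `row`, `col` (1-based offsets).
#' @export
detector_layout <- function(module_ids, module_dims = c(514L, 1030L),
                            gap = c(36L, 8L), ncol_modules = 2L) {
  n <- length(module_ids)
  grid_r <- (seq_len(n) - 1L) %/% ncol_modules
  grid_c <- (seq_len(n) - 1L) %% ncol_modules
  data.frame(module_id = module_ids,
             row = 1L + grid_r * (module_dims[1] + gap[1]),
             col = 1L + grid_c * (module_dims[2] + gap[2]))
}

#' Assemble expanded module frames into a full detector image
#'
#' Modules are placed at their layout offsets; pixels not covered by any
#' module (inter-module gaps) are masked.  A module missing from `frames`
#' leaves its region masked with a warning.
#'
#' @param frames Named list of expanded [photon_frame()] objects, names =
#'   module ids.
#' @param layout Data frame from [detector_layout()].
#' @return The assembled [photon_frame()].
#' @export
assemble_detector <- function(frames, layout) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]]$values)
  u <- frames[[1]]$unit
  span <- frames[[1]]$angular_span
  H <- max(layout$row) + d[1] - 1L
  W <- max(layout$col) + d[2] - 1L
  v <- matrix(NA_real_, H, W)
  mask <- matrix(TRUE, H, W)
  for (i in seq_len(nrow(layout))) {
    id <- as.character(layout$module_id[i])
    f <- frames[[id]]
    if (is.null(f)) {
      warning(sprintf("module %s missing; region left masked", id))
      next
    }
    stopifnot(identical(dim(f$values), d), f$unit == u, f$expanded)
    rr <- layout$row[i]:(layout$row[i] + d[1] - 1L)
    cc <- layout$col[i]:(layout$col[i] + d[2] - 1L)
    v[rr, cc] <- f$values
    mask[rr, cc] <- f$mask
  }
  photon_frame(v, unit = u, mask = mask, angular_span = span, expanded = TRUE)
}
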