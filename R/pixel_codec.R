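#' Gain level names
#'
#' The three amplification modes a pixel selects automatically: G0 is the
#' most sensitive (single-photon), G1 and G2 extend the dynamic range up to
#' roughly 10^4 photons at 12.4 keV.
#'
#' @return `c("G0", "G1", "G2")`.
#' @export
gain_levels <- function() c("G0", "G1", "G2")

# 2-bit gain codes in the top bits of the pixel word: 00-G0, 01-G1, 11-G2.
# Code 10 is never emitted by the detector and is treated as invalid.
GAIN_CODE <- c(G0 = 0L, G1 = 1L, G2 = 3L)

#' Decode a 16-bit pixel word
#'
#' The first two bits of the word encode the gain level (00-G0, 01-G1,
#' 11-G2) and the remaining 14 bits the accumulated charge in ADU.
#' The unused code 10 yields gain `NA`: an invalid pixel.
#'
#' @param word Integer vector of pixel words in `[0, 65535]`.
#' @return List with `gain` (character, `NA` for invalid code), `adu`
#'   (integer in `[0, 16383]`) and `invalid` (logical).
#' @examples
#' decode_word(0xC005L)  # G2, 5 ADU
#' @export
decode_word <- function(word) {
  word <- as.integer(word)
  if (any(word < 0L | word > 65535L, na.rm = TRUE))
    stop("pixel words must be in [0, 65535]")
  code <- word %/% 16384L
  adu <- word - code * 16384L
  gain <- c("G0", "G1", NA_character_, "G2")[code + 1L]
  list(gain = gain, adu = adu, invalid = is.na(gain) & !is.na(word))
}

#' Encode a gain level and ADU value into a pixel word
#'
#' Inverse of [decode_word()]; used by the simulator and stream tooling.
#'
#' @param gain Character vector of gain levels (`"G0"`, `"G1"`, `"G2"`) or
#'   integer gain indices 1:3.
#' @param adu Integer ADU values in `[0, 16383]`.
#' @return Integer pixel words.
#' @export
encode_word <- function(gain, adu) {
  if (is.numeric(gain)) gain <- gain_levels()[gain]
  code <- GAIN_CODE[gain]
  if (anyNA(code)) stop("unknown gain level")
  adu <- as.integer(adu)
  if (any(adu < 0L | adu > 16383L))
    stop("adu out of range [0, 16383]")
  as.integer(unname(code) * 16384L + adu)
}

#' Decode a raw frame into gain and ADU maps
#'
#' Element-wise [decode_word()] over a module frame.  Pixels with the
#' invalid gain code 10 (and pixels lost in transport, stored as `NA`) are
#' masked rather than fatal; the count is reported via the mask.
#'
#' @param frame A [raw_frame()].
#' @return List with `gain` (integer matrix of gain indices 1:3, `NA` where
#'   invalid), `adu` (integer matrix) and `invalid` (logical matrix,
#'   invalid gain code or missing pixel).
#' @export
decode_frame <- function(frame) {
  stopifnot(inherits(frame, "jf_raw_frame"))
  w <- frame$pixels
  code <- w %/% 16384L
  adu <- w - code * 16384L
  gain <- matrix(c(1L, 2L, NA_integer_, 3L)[code + 1L], nrow = nrow(w))
  invalid <- is.na(gain)
  list(gain = gain, adu = adu, invalid = invalid)
}
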