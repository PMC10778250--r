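#' Temperature bin edges of the Pixel-Counting Protocol
#'
#' Five 2-degree bins spanning the rendering range 28.0-38.0 C. The first
#' four bins are half-open `[lo, hi)`; the top bin is closed `[36, 38]`.
#'
#' @return data.frame with columns bin, t_lo, t_hi.
#' @export
pcp_bins <- function() {
  data.frame(bin = 1:5, t_lo = c(28, 30, 32, 34, 36),
             t_hi = c(30, 32, 34, 36, 38))
}

#' Temperature bin of a pixel temperature
#'
#' Bins are `[28,30)`, `[30,32)`, `[32,34)`, `[34,36)`, `[36,38]`.
#' Temperatures below 28 C are background (coded 0): the rendering range
#' starts at 28, below which pixels are blacked out. Temperatures above
#' 38 C clamp to bin 5, mirroring the camera software's clipped range.
#'
#' @param t Numeric vector of temperatures in degrees C.
#' @return Integer vector of bin indices 1-5, with 0 for background.
#' @examples
#' bin_of_temperature(c(29, 30, 38))  # 1 2 5
#' @export
bin_of_temperature <- function(t) {
  if (any(!is.finite(t))) stop("temperatures must be finite")
  b <- findInterval(t, c(28, 30, 32, 34, 36))
  b[t > 38] <- 5L
  as.integer(b)
}

#' The bundled pseudocolor palette
#'
#' A deterministic stand-in for the proprietary camera-software palette:
#' within each 2-degree bin the color ramps linearly in sRGB between two
#' stops of that bin's color family (purple/navy, blue, green,
#' yellow/orange, red), with a hard family change at each bin edge. The
#' hard edges guarantee that every rendered color classifies back (by
#' nearest CIE76 reference) to the bin of the temperature that produced
#' it. Background is exact #000000.
#'
#' @return Object of class `pcp_palette`: a data.frame with bin, t_lo,
#'   t_hi, hex_lo, hex_hi, and attributes `t_min`, `t_max`.
#' @export
default_palette <- function() {
  stops <- data.frame(
    bin = 1:5, t_lo = c(28, 30, 32, 34, 36), t_hi = c(30, 32, 34, 36, 38),
    hex_lo = c("#38004C", "#0000FF", "#007800", "#FFFF00", "#FF2000"),
    hex_hi = c("#000090", "#0090FF", "#00E000", "#FF8000", "#A00000"),
    stringsAsFactors = FALSE)
  .as_pcp_palette(stops)
}

.as_pcp_palette <- function(stops) {
  stopifnot(all(c("bin", "t_lo", "t_hi", "hex_lo", "hex_hi") %in% names(stops)))
  if (any(diff(stops$t_lo) <= 0) || any(stops$t_hi <= stops$t_lo))
    stop("palette stops must be strictly increasing in temperature")
  structure(stops, t_min = min(stops$t_lo), t_max = max(stops$t_hi),
            class = c("pcp_palette", "data.frame"))
}

#' Load a palette from a stops file
#'
#' The file is a CSV with columns `bin, t_lo, t_hi, hex_lo, hex_hi`: one
#' linear sRGB ramp per temperature bin.
#'
#' @param path CSV file path.
#' @return A `pcp_palette` (see [default_palette()]).
#' @export
read_palette <- function(path) {
  .as_pcp_palette(utils::read.csv(path, stringsAsFactors = FALSE))
}

.hex_to_rgb <- function(hex) t(grDevices::col2rgb(hex))

#' Palette color at given temperatures
#'
#' Linear interpolation within each bin's sRGB ramp, quantized to 8-bit
#' channels by round-half-up. Temperatures below `t_min` map to the
#' background #000000; above `t_max` they clamp to the top of the red
#' ramp.
#'
#' @param t Numeric vector of temperatures (degrees C).
#' @param palette A `pcp_palette`, default [default_palette()].
#' @return n x 3 integer matrix (columns r, g, b in 0-255).
#' @export
palette_color_at <- function(t, palette = default_palette()) {
  if (any(!is.finite(t))) stop("temperatures must be finite")
  b <- bin_of_temperature(pmin(t, attr(palette, "t_max")))
  out <- matrix(0L, length(t), 3L, dimnames = list(NULL, c("r", "g", "b")))
  surf <- b > 0L
  if (any(surf)) {
    lo <- .hex_to_rgb(palette$hex_lo[b[surf]])
    hi <- .hex_to_rgb(palette$hex_hi[b[surf]])
    tt <- pmin(t[surf], attr(palette, "t_max"))
    u <- (tt - palette$t_lo[b[surf]]) / (palette$t_hi[b[surf]] - palette$t_lo[b[surf]])
    out[surf, ] <- matrix(as.integer(floor(lo + u * (hi - lo) + 0.5)),
                          ncol = 3L)
  }
  out
}

#' Reference colors of the five temperature bins
#'
#' The palette sampled at each bin's temperature midpoint (29, 31, 33,
#' 35, 37 C); the CIE76 nearest-reference targets of [classify_color()].
#'
#' @param palette A `pcp_palette`.
#' @return 5 x 3 integer RGB matrix.
#' @export
bin_reference_colors <- function(palette = default_palette()) {
  palette_color_at((palette$t_lo + palette$t_hi) / 2, palette)
}
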