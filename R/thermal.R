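#' Construct a thermal scene
#'
#' A scene is a per-pixel temperature field in degrees C (matrix rows =
#' image rows, top to bottom) plus a surface mask. Unmasked (background)
#' pixels may be `NA`. Pixels below 28 C are also background: the
#' rendering range is clipped at 28.
#'
#' @param temperatures Numeric h x w matrix; `NA` allowed off-surface.
#' @param mask Logical h x w matrix, `TRUE` on the body surface; default:
#'   finite temperature pixels.
#' @return Object of class `thermal_scene`: `temperatures`, `mask`,
#'   `width`, `height`.
#' @export
thermal_scene <- function(temperatures, mask = NULL) {
  temperatures <- as.matrix(temperatures)
  if (is.null(mask)) mask <- is.finite(temperatures)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(temperatures)))
    stop("mask and temperature grid must be congruent")
  if (any(mask & !is.finite(temperatures)))
    stop("surface pixels must have finite temperatures")
  structure(list(temperatures = temperatures, mask = mask,
                 width = ncol(temperatures), height = nrow(temperatures)),
            class = "thermal_scene")
}

#' @export
print.thermal_scene <- function(x, ...) {
  cat("<thermal_scene> ", x$width, " x ", x$height, " px, ",
      sum(x$mask), " surface pixels", sep = "")
  if (any(x$mask))
    cat(", T in [", format(min(x$temperatures[x$mask]), digits = 4), ", ",
        format(max(x$temperatures[x$mask]), digits = 4), "] C", sep = "")
  cat("\n")
  invisible(x)
}

#' Render a thermal scene to a pseudocolor RGB raster
#'
#' Surface pixels are colored through the palette at their temperature;
#' background pixels (masked, or below the 28 C threshold) are exact
#' #000000.
#'
#' @param scene A [thermal_scene()].
#' @param palette A `pcp_palette`, default [default_palette()].
#' @return h x w x 3 integer array, channels 0-255.
#' @export
render_thermogram <- function(scene, palette = default_palette()) {
  stopifnot(inherits(scene, "thermal_scene"))
  h <- scene$height; w <- scene$width
  img <- array(0L, dim = c(h, w, 3L))
  surf <- which(scene$mask & scene$temperatures >= attr(palette, "t_min"))
  if (length(surf)) {
    cols <- palette_color_at(scene$temperatures[surf], palette)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[surf] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Surface mask of a rendered thermogram
#'
#' All and only pixels with exact value #000000 are background; anything
#' else (including near-black #010101) is body surface.
#'
#' @param image h x w x 3 RGB array (0-255).
#' @return Logical h x w matrix, `TRUE` on surface.
#' @export
mask_background <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an h x w x 3 RGB array")
  surface <- image[, , 1] != 0L | image[, , 2] != 0L | image[, , 3] != 0L
  if (!any(surface)) stop("empty surface: every pixel is #000000")
  surface
}

#' Exact color histogram of the surface pixels
#'
#' @param image h x w x 3 RGB array (0-255).
#' @param surface Logical h x w surface mask, default [mask_background()].
#' @return data.frame with columns r, g, b, count; counts sum to the
#'   surface size.
#' @export
extract_color_histogram <- function(image, surface = mask_background(image)) {
  idx <- which(surface)
  if (!length(idx)) stop("empty surface")
  key <- image[, , 1][idx] * 65536L + image[, , 2][idx] * 256L + image[, , 3][idx]
  tab <- table(key)
  keys <- as.integer(names(tab))
  data.frame(r = keys %/% 65536L, g = (keys %/% 256L) %% 256L,
             b = keys %% 256L, count = as.integer(tab))
}

#' Per-bin surface profile of a thermogram
#'
#' The Pixel-Counting Protocol output for one image: the exact color
#' histogram of the non-#000000 surface is classified color-by-color into
#' the five temperature bins ([classify_color()]), and per-bin pixel
#' counts are reported as percentages of the total surface pixels.
#'
#' @param image h x w x 3 RGB array (0-255).
#' @param palette A `pcp_palette`, default [default_palette()].
#' @return Object of class `surface_profile`: `counts` (length 5),
#'   `total_surface_pixels`, `percentages` (sum to 100).
#' @export
surface_profile <- function(image, palette = default_palette()) {
  hist <- extract_color_histogram(image)
  bins <- classify_color(as.matrix(hist[, c("r", "g", "b")]), palette)
  counts <- vapply(1:5, function(b) sum(hist$count[bins == b]), integer(1))
  total <- sum(hist$count)
  structure(list(counts = counts, total_surface_pixels = total,
                 percentages = 100 * counts / total),
            class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  bins <- pcp_bins()
  cat("<surface_profile> ", x$total_surface_pixels, " surface pixels\n",
      sep = "")
  for (b in 1:5)
    cat(sprintf("  T in [%g, %g%s: %7d px  %6.2f%%\n", bins$t_lo[b],
                bins$t_hi[b], if (b == 5) "]" else ")", x$counts[b],
                x$percentages[b]))
  invisible(x)
}

#' Direct per-pixel temperature-bin tally of a scene
#'
#' Counts surface pixels per temperature bin straight from the
#' temperature field, bypassing rendering and color classification; the
#' two routes agree pixel-exactly for any scene.
#'
#' @param scene A [thermal_scene()].
#' @return Integer vector of length 5.
#' @export
temperature_bin_tally <- function(scene) {
  t_surf <- scene$temperatures[scene$mask]
  b <- bin_of_temperature(t_surf)
  vapply(1:5, function(i) sum(b == i), integer(1))
}

#' Profile as a data.frame (the CSV layout)
#' @param profile A [surface_profile()].
#' @return data.frame with bin, t_lo, t_hi, count, percent.
#' @export
profile_to_df <- function(profile) {
  cbind(pcp_bins(), count = profile$counts, percent = profile$percentages)
}

#' Pie chart of a surface profile
#'
#' Five sectors with angles proportional to the bin percentages, colored
#' by the bin reference colors; zero-count bins keep their (zero-angle)
#' slot and label. Returns the deterministic sector table driving the
#' chart.
#'
#' @param profile A [surface_profile()].
#' @param palette A `pcp_palette` (colors the sectors).
#' @param plot If `TRUE` (default), draw the chart on the active device.
#' @return data.frame with bin, label, percent, angle_deg, color
#'   (invisibly when `plot = TRUE`).
#' @export
profile_to_pie <- function(profile, palette = default_palette(), plot = TRUE) {
  bins <- pcp_bins()
  refs <- bin_reference_colors(palette)
  sectors <- data.frame(
    bin = bins$bin,
    label = sprintf("T in [%g, %g%s", bins$t_lo, bins$t_hi,
                    ifelse(bins$bin == 5, "]", ")")),
    percent = profile$percentages,
    angle_deg = 360 * profile$percentages / 100,
    color = grDevices::rgb(refs[, 1], refs[, 2], refs[, 3],
                           maxColorValue = 255),
    stringsAsFactors = FALSE)
  if (plot) {
    nonzero <- profile$counts > 0
    graphics::pie(profile$percentages[nonzero],
                  labels = sprintf("%s  %.1f%%", sectors$label[nonzero],
                                   sectors$percent[nonzero]),
                  col = sectors$color[nonzero], clockwise = TRUE)
    return(invisible(sectors))
  }
  sectors
}

#' Read an RGB thermogram from a PNG file
#'
#' Lossless 8-bit RGB input for the Pixel-Counting Protocol. Lossy
#' formats are not supported: compression quantization can move pixel
#' colors across bin boundaries.
#'
#' @param path PNG file path.
#' @return h x w x 3 integer array (0-255).
#' @export
read_thermogram_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) stop("grayscale PNG: need an RGB thermogram")
  arr <- array(as.integer(round(img[, , 1:3] * 255)), dim = c(dim(img)[1:2], 3L))
  arr
}

#' Write an RGB thermogram to a PNG file
#' @param image h x w x 3 integer array (0-255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a raw temperature field from CSV
#'
#' Numeric grid, one row per image row (top first), commas between
#' columns; empty cells or `NA` are background.
#'
#' @param path CSV file path.
#' @return A [thermal_scene()].
#' @export
read_temperature_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  thermal_scene(m)
}
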