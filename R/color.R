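#' Convert sRGB colors to CIELAB
#'
#' Standard conversion: 8-bit sRGB channels are linearized with the
#' IEC 61966-2-1 transfer function (2.4-exponent branch below the 0.04045
#' cut), mapped to CIE XYZ with the D65 sRGB matrix, and converted to
#' L*a*b* against the D65 white point. L* is perceptual lightness in
#' [0, 100]; a* and b* are the opponent red-green and yellow-blue axes.
#'
#' @param rgb Integer vector of length 3 or n x 3 matrix, channels 0-255.
#' @return n x 3 matrix with columns L, a, b.
#' @examples
#' srgb_to_lab(c(255, 255, 255))  # L = 100, a ~ 0, b ~ 0
#' @export
srgb_to_lab <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3L, byrow = TRUE)
  if (ncol(m) != 3L) stop("`rgb` must have three channels")
  if (any(m < 0 | m > 255)) stop("channels must be in 0..255")
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3L, 3L, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.4124564 + 0.3575761 + 0.1804375,
             0.2126729 + 0.7151522 + 0.0721750,
             0.0193339 + 0.1191920 + 0.9503041)
  xyz <- sweep(xyz, 2L, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  out
}

#' CIE76 color difference
#'
#' The Euclidean distance in CIELAB,
#' `deltaE = sqrt(dL^2 + da^2 + db^2)`; the original (1976) CIE color
#' difference formula.
#'
#' @param c1,c2 Length-3 Lab triples or n x 3 Lab matrices (recycled
#'   row-wise).
#' @return Non-negative numeric vector of distances.
#' @examples
#' delta_e76(c(50, 0, 0), c(60, 0, 0))    # 10
#' delta_e76(c(50, 10, 10), c(53, 14, 22)) # 13
#' @export
delta_e76 <- function(c1, c2) {
  m1 <- if (is.matrix(c1)) c1 else matrix(c1, ncol = 3L, byrow = TRUE)
  m2 <- if (is.matrix(c2)) c2 else matrix(c2, ncol = 3L, byrow = TRUE)
  if (!all(is.finite(m1)) || !all(is.finite(m2)))
    stop("Lab coordinates must be finite")
  n <- max(nrow(m1), nrow(m2))
  if (nrow(m1) == 1L) m1 <- m1[rep(1L, n), , drop = FALSE]
  if (nrow(m2) == 1L) m2 <- m2[rep(1L, n), , drop = FALSE]
  sqrt(rowSums((m1 - m2)^2))
}

#' Classify pixel colors into temperature bins
#'
#' Converts each color to CIELAB and assigns it to the temperature bin
#' whose reference color ([bin_reference_colors()], the palette at the
#' bin's midpoint) minimizes the CIE76 distance. Ties break toward the
#' lower bin. The background color #000000 is not classifiable.
#'
#' @param rgb Length-3 RGB triple or n x 3 matrix, channels 0-255.
#' @param palette A `pcp_palette`, default [default_palette()].
#' @return Integer vector of bin indices 1-5.
#' @export
classify_color <- function(rgb, palette = default_palette()) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3L, byrow = TRUE)
  if (any(rowSums(m) == 0))
    stop("#000000 is the background color and cannot be classified")
  lab <- srgb_to_lab(m)
  refs <- srgb_to_lab(bin_reference_colors(palette))
  d2 <- outer(rowSums(lab^2), rep(1, 5)) - 2 * lab %*% t(refs) +
    outer(rep(1, nrow(lab)), rowSums(refs^2))
  as.integer(max.col(-d2, ties.method = "first"))
}
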