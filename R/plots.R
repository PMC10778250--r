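#' Wireframe plot of a consensus shape and a deformed shape
#'
#' Draws the 30-point dorsal-profile polyline of a reference shape (light
#' blue) and, optionally, a deformation of it (dark blue): either a
#' per-class consensus or the consensus displaced along a PC vector.
#'
#' @param reference k x 2 matrix (e.g. the GPA consensus).
#' @param deformed Optional k x 2 matrix drawn over the reference.
#' @param main Plot title.
#' @param region_breaks Draw dashed separators between the hindquarter,
#'   back, and head/neck regions (default `TRUE`).
#' @export
plot_wireframe <- function(reference, deformed = NULL, main = "",
                           region_breaks = TRUE) {
  rng <- rbind(reference, deformed)
  graphics::plot(rng[, 1], rng[, 2], type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  graphics::lines(reference[, 1], reference[, 2], col = "#8FC9E8", lwd = 2)
  graphics::points(reference[, 1], reference[, 2], col = "#8FC9E8", pch = 16,
                   cex = 0.6)
  if (!is.null(deformed)) {
    graphics::lines(deformed[, 1], deformed[, 2], col = "#1F4E79", lwd = 2)
    graphics::points(deformed[, 1], deformed[, 2], col = "#1F4E79", pch = 16,
                     cex = 0.6)
  }
  if (region_breaks) {
    for (cut in c(8.5, 19.5)) {
      lo <- reference[floor(cut), ]; hi <- reference[ceiling(cut), ]
      mid <- (lo + hi) / 2
      graphics::abline(v = mid[1], lty = 2, col = "grey70")
    }
  }
  invisible(NULL)
}

#' Shape deformation along a principal component
#'
#' The consensus displaced by `magnitude` times the unit deformation
#' vector of one PC, reshaped to landmark coordinates for wireframe
#' display.
#'
#' @param pca_res A [pca()] result.
#' @param component PC index.
#' @param magnitude Displacement in score units (e.g. 3 SDs of that PC's
#'   scores).
#' @return k x 2 matrix.
#' @export
pc_deformation <- function(pca_res, component, magnitude) {
  v <- pca_res$vectors[, component]
  k <- pca_res$k
  pca_res$consensus + magnitude * cbind(v[seq_len(k)], v[k + seq_len(k)])
}

#' Scatter plot of PC scores with group confidence ellipses
#'
#' @param scores n x 2 matrix of scores on two PCs.
#' @param labels Grouping vector.
#' @param probability Ellipse coverage probability (default 0.9).
#' @param xlab,ylab,main Plot annotation.
#' @export
plot_scores_ellipses <- function(scores, labels, probability = 0.9,
                                 xlab = "PC1", ylab = "PC2", main = "") {
  labels <- droplevels(as.factor(labels))
  cols <- grDevices::hcl.colors(nlevels(labels), "Dark 3")
  graphics::plot(scores[, 1], scores[, 2], col = cols[labels], pch = 16,
                 xlab = xlab, ylab = ylab, main = main)
  for (li in seq_len(nlevels(labels))) {
    pts <- scores[labels == levels(labels)[li], , drop = FALSE]
    if (nrow(pts) < 3L) next
    ell <- try(confidence_ellipse(pts, probability), silent = TRUE)
    if (inherits(ell, "try-error")) next
    bnd <- ellipse_boundary(ell)
    graphics::lines(bnd[, 1], bnd[, 2], col = cols[li], lwd = 2)
  }
  graphics::legend("topright", legend = levels(labels), col = cols,
                   pch = 16, bty = "n")
  invisible(NULL)
}

#' Box plots of bin percentages with significance letters
#'
#' Median/quartile boxes with whiskers at the minimum and maximum (no
#' outlier trimming) and lowercase compact-letter annotations above each
#' box.
#'
#' @param values Numeric vector of percentages.
#' @param groups Grouping vector (ranges or subsets).
#' @param cld Named character vector of letters per group (from
#'   [compact_letters()]); optional.
#' @param ylab,main Plot annotation.
#' @export
plot_profile_box <- function(values, groups, cld = NULL,
                             ylab = "% of surface pixels", main = "") {
  groups <- droplevels(as.factor(groups))
  graphics::boxplot(values ~ groups, range = 0, ylab = ylab, main = main,
                    col = "grey90")
  if (!is.null(cld)) {
    tops <- tapply(values, groups, max)
    pad <- 0.04 * diff(range(values))
    graphics::text(seq_len(nlevels(groups)), tops + pad,
                   cld[levels(groups)], font = 3)
  }
  invisible(NULL)
}
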