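#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks to their
#' centroid; the size measure removed by Procrustes superimposition.
#'
#' @param config A [landmark_config()] or a numeric k x 2 matrix.
#' @return Positive scalar.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  pts <- if (inherits(config, "landmark_config")) config$points else as.matrix(config)
  if (nrow(pts) < 2L) stop("need at least 2 points")
  cen <- colMeans(pts)
  cs <- sqrt(sum(sweep(pts, 2L, cen)^2))
  if (cs < .Machine$double.eps^0.5 * nrow(pts))
    stop("degenerate configuration: all points (near-)coincident")
  cs
}

# --- complex-plane helpers (2-D shapes as complex k-vectors) -------------

.to_complex <- function(pts) complex(real = pts[, 1], imaginary = pts[, 2])
.from_complex <- function(z) cbind(x = Re(z), y = Im(z))

# center at origin and scale to unit centroid size
.center_scale <- function(z) {
  z <- z - mean(z)
  s <- sqrt(sum(Mod(z)^2))
  if (s == 0) stop("degenerate configuration: zero centroid size")
  z / s
}

#' Align one configuration to a reference (ordinary Procrustes step)
#'
#' Translates the target to a common centroid, scales it to unit centroid
#' size, and rotates it (proper rotation only, no reflection) to minimize
#' the summed squared landmark distances to the reference, which is itself
#' centered and scaled. Returns the aligned target and the minimized root
#' distance (the partial Procrustes distance between the two shapes).
#'
#' @param reference,target [landmark_config()] objects or k x 2 matrices
#'   with the same landmark count.
#' @return List with `aligned` (k x 2 matrix, unit centroid size) and
#'   `distance` (non-negative scalar).
#' @export
align_pair <- function(reference, target) {
  ref <- if (inherits(reference, "landmark_config")) reference$points else as.matrix(reference)
  tar <- if (inherits(target, "landmark_config")) target$points else as.matrix(target)
  if (nrow(ref) != nrow(tar)) stop("landmark counts differ")
  w <- .center_scale(.to_complex(ref))
  z <- .center_scale(.to_complex(tar))
  # optimal proper rotation e^{i*theta}: phase of <w, z>
  s <- sum(w * Conj(z))
  rot <- if (Mod(s) == 0) 1 + 0i else s / Mod(s)
  aligned <- z * rot
  d <- sqrt(sum(Mod(aligned - w)^2))
  list(aligned = .from_complex(aligned), distance = d)
}

#' Dimension of shape space
#'
#' Number of independent shape coordinates for `k` landmarks in `d`
#' dimensions after removing translation (`d`), rotation (`d(d-1)/2`) and
#' scale (1): `d*k - d - d(d-1)/2 - 1`. For 30 two-dimensional landmarks
#' this is 56, the per-group shape degrees of freedom multiplier in
#' Procrustes ANOVA.
#'
#' @param k Landmark count (>= 3).
#' @param d Spatial dimension, 2 or 3.
#' @return Integer.
#' @examples
#' shape_dimension(30, 2)  # 56
#' shape_dimension(3, 2)   # 2 (triangle shape space)
#' @export
shape_dimension <- function(k, d = 2L) {
  k <- as.integer(k); d <- as.integer(d)
  if (k < 3L) stop("`k` must be >= 3")
  if (!d %in% c(2L, 3L)) stop("`d` must be 2 or 3")
  d * k - d - (d * (d - 1L)) %/% 2L - 1L
}

#' Generalized Procrustes Analysis
#'
#' Iterative superimposition of a landmark dataset: every configuration is
#' centered and scaled to unit centroid size, rotated to the current
#' consensus, and the consensus recomputed, until the consensus moves by
#' less than `tol` (default 1e-8) or `max_iter` iterations are reached.
#' Rotations are proper (no reflection); scale is removed by unit centroid
#' size. Centroid sizes before scaling are recorded for size analysis.
#'
#' @param dataset A [landmark_dataset()] (or k x 2 x n array).
#' @param tol Convergence tolerance on the root-summed-squared consensus
#'   displacement.
#' @param max_iter Maximum number of iterations.
#' @return Object of class `procrustes_fit`: `consensus` (k x 2, centroid
#'   at origin, unit size), `aligned` (k x 2 x n array of superimposed
#'   coordinates), `centroid_sizes` (length n), `n_iterations`,
#'   `converged`, and the dataset `meta` if present.
#' @export
gpa <- function(dataset, tol = 1e-8, max_iter = 100L) {
  coords <- if (inherits(dataset, "landmark_dataset")) dataset$coords else dataset
  meta <- if (inherits(dataset, "landmark_dataset")) dataset$meta else NULL
  n <- dim(coords)[3]
  k <- dim(coords)[1]
  if (is.null(n) || n < 2L) stop("GPA needs at least 2 configurations")
  # Z: n x k complex matrix of centered, unit-size configurations
  Z <- matrix(NA_complex_, n, k)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    z <- .to_complex(coords[, , i])
    z <- z - mean(z)
    s <- sqrt(sum(Mod(z)^2))
    if (s == 0) stop("configuration ", i, " is degenerate (zero centroid size)")
    sizes[i] <- s
    Z[i, ] <- z / s
  }
  consensus <- Z[1, ]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # optimal rotations of every row onto the consensus, vectorized
    s <- Conj(Z) %*% consensus            # n x 1: sum_j w_j * conj(z_ij)
    rot <- as.vector(s) / Mod(as.vector(s))
    rot[!is.finite(rot)] <- 1 + 0i
    Z <- Z * rot
    new_consensus <- colMeans(Z)
    new_consensus <- new_consensus - mean(new_consensus)
    ns <- sqrt(sum(Mod(new_consensus)^2))
    if (ns == 0) stop("degenerate consensus")
    new_consensus <- new_consensus / ns
    delta <- sqrt(sum(Mod(new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  aligned <- array(NA_real_, dim = c(k, 2L, n),
                   dimnames = list(NULL, c("x", "y"), NULL))
  for (i in seq_len(n)) aligned[, , i] <- .from_complex(Z[i, ])
  structure(list(consensus = .from_complex(consensus), aligned = aligned,
                 centroid_sizes = sizes, n_iterations = iter,
                 converged = converged, meta = meta),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> ", dim(x$aligned)[3], " configurations of ",
      dim(x$aligned)[1], " landmarks; ", x$n_iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

# n x 2k matrix of aligned coordinates (x1..xk then y1..yk per row? no:
# interleaved x,y per landmark) used by PCA and Procrustes ANOVA.
.flatten_fit <- function(fit) {
  n <- dim(fit$aligned)[3]
  t(apply(fit$aligned, 3L, as.vector))  # columns: x1..xk, y1..yk
}
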