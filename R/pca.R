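#' Principal component analysis of Procrustes coordinates
#'
#' Eigendecomposition of the covariance matrix of the superimposed
#' coordinates about the consensus. Percentages of variance are
#' eigenvalues over the total variance (the trace of the covariance
#' matrix) times 100. Scores are the projections of the centered
#' coordinates on the unit-norm deformation vectors. The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' At most `min(n - 1, shape_dimension(k, 2))` eigenvalues are nonzero:
#' superimposition removes translation, rotation and scale from the
#' 2k-dimensional coordinate space.
#'
#' Superimposed coordinates are first projected orthogonally into the
#' tangent space at the consensus (removing the residual scale and
#' rotation directions left by the nonlinear unit-size constraint), so
#' the coordinate matrix has rank at most `shape_dimension(k, 2)` exactly
#' and the reconstruction identity holds to machine precision.
#'
#' @param fit A [gpa()] fit.
#' @return Object of class `shape_pca`: `eigenvalues` (descending),
#'   `pct_variance`, `cum_pct`, `scores` (n x m), `vectors` (2k x m
#'   orthonormal columns), `total_variance`, `center`, `tangent_coords`
#'   (n x 2k, the projected coordinates the decomposition acts on),
#'   `consensus`, `k`.
#' @export
pca <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  X <- .flatten_fit(fit)
  n <- nrow(X)
  if (n < 3L) stop("PCA needs at least 3 specimens")
  # tangent projection: remove the scale (consensus) and rotation
  # (i * consensus) directions from the deviations
  w <- fit$consensus
  v1 <- c(w[, 1], w[, 2]); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(-w[, 2], w[, 1]); v2 <- v2 / sqrt(sum(v2^2))
  mu0 <- colMeans(X)
  D <- sweep(X, 2L, mu0)
  D <- D - (D %*% v1) %*% t(v1) - (D %*% v2) %*% t(v2)
  X <- sweep(D, 2L, mu0, "+")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  V <- stats::cov(X)
  total <- sum(diag(V))
  if (total <= 0) stop("zero total variance: all shapes identical")
  eig <- eigen(V, symmetric = TRUE)
  m <- min(n - 1L, shape_dimension(dim(fit$aligned)[1], 2L))
  vals <- pmax(eig$values, 0)[seq_len(m)]
  vecs <- eig$vectors[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(m)) {
    peak <- which.max(abs(vecs[, j]))
    if (vecs[peak, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- Xc %*% vecs
  pct <- 100 * vals / total
  structure(list(eigenvalues = vals, pct_variance = pct,
                 cum_pct = cumsum(pct), scores = scores, vectors = vecs,
                 total_variance = total, center = mu, tangent_coords = X,
                 consensus = fit$consensus, k = dim(fit$aligned)[1]),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("<shape_pca> total variance ", format(x$total_variance, digits = 4),
      "\n", sep = "")
  n_show <- min(3L, length(x$eigenvalues))
  for (j in seq_len(n_show))
    cat(sprintf("  PC%d: eigenvalue %.6g, %.2f%%, cumulative %.2f%%\n",
                j, x$eigenvalues[j], x$pct_variance[j], x$cum_pct[j]))
  invisible(x)
}

#' PC summary table
#' @param pca_res A [pca()] result.
#' @return data.frame with component, eigenvalue, pct, cum_pct.
#' @export
pc_summary <- function(pca_res) {
  data.frame(component = seq_along(pca_res$eigenvalues),
             eigenvalue = pca_res$eigenvalues,
             pct = pca_res$pct_variance,
             cum_pct = pca_res$cum_pct)
}

#' Variance of the eigenvalue spectrum, under three scalings
#'
#' Summaries of morphological integration computed from a PCA spectrum:
#' the raw variance of the eigenvalues, the same scaled by the squared
#' total variance, and a standardized index additionally normalized by the
#' number of variables. Conventions: the raw variance uses the population
#' (divide-by-p) form over the p reported eigenvalues; the standardized
#' index multiplies the scaled variance by p^2 / (p - 1), i.e. the
#' variance of the eigenvalues of the correlation-like rescaled spectrum
#' relative to its maximum possible value.
#'
#' @param eigenvalues Non-negative eigenvalue sequence.
#' @param total_variance Trace of the coordinate covariance matrix
#'   (defaults to `sum(eigenvalues)`).
#' @param n_variables Number of variables behind the spectrum (defaults to
#'   `length(eigenvalues)`).
#' @return List with `raw`, `scaled_by_total`, `standardized`.
#' @export
eigenvalue_variance_stats <- function(eigenvalues,
                                      total_variance = sum(eigenvalues),
                                      n_variables = length(eigenvalues)) {
  p <- length(eigenvalues)
  if (p < 1L) stop("need at least one eigenvalue")
  if (p == 1L) return(list(raw = 0, scaled_by_total = 0, standardized = 0))
  m <- mean(eigenvalues)
  raw <- sum((eigenvalues - m)^2) / p
  scaled <- raw / total_variance^2
  standardized <- scaled * n_variables^2 / (n_variables - 1)
  list(raw = raw, scaled_by_total = scaled, standardized = standardized)
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Ellipse from the group mean and covariance whose squared Mahalanobis
#' radius equals the chi-square (2 df) quantile at the given probability:
#' the standard Gaussian-coverage ellipse drawn around grouped PC scores
#' (probability 0.9 in the posture plots).
#'
#' @param scores n x 2 matrix of 2-D scores (n >= 3).
#' @param probability Coverage probability, default 0.9.
#' @return Object of class `confidence_ellipse`: `center`, `semi_axes`
#'   (descending), `orientation` (radians, direction of the major axis),
#'   `probability`.
#' @export
confidence_ellipse <- function(scores, probability = 0.9) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("`scores` must have two columns")
  if (nrow(scores) < 3L) stop("need at least 3 points")
  V <- stats::cov(scores)
  if (abs(det(V)) < .Machine$double.eps) stop("singular score covariance")
  eig <- eigen(V, symmetric = TRUE)
  if (any(eig$values <= 0)) stop("singular score covariance")
  r2 <- stats::qchisq(probability, df = 2)
  structure(list(center = colMeans(scores),
                 semi_axes = sqrt(eig$values * r2),
                 orientation = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
                 probability = probability),
            class = "confidence_ellipse")
}

#' Points on the boundary of a confidence ellipse
#' @param ellipse A [confidence_ellipse()].
#' @param n Number of boundary points.
#' @return n x 2 matrix.
#' @export
ellipse_boundary <- function(ellipse, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  phi <- ellipse$orientation
  x <- a * cos(th); y <- b * sin(th)
  cbind(ellipse$center[1] + x * cos(phi) - y * sin(phi),
        ellipse$center[2] + x * sin(phi) + y * cos(phi))
}

#' Is a point inside a confidence ellipse?
#' @param ellipse A [confidence_ellipse()].
#' @param pts n x 2 matrix of points.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, pts) {
  pts <- matrix(pts, ncol = 2L)
  phi <- ellipse$orientation
  d <- sweep(pts, 2L, ellipse$center)
  u <- d[, 1] * cos(phi) + d[, 2] * sin(phi)
  v <- -d[, 1] * sin(phi) + d[, 2] * cos(phi)
  (u / ellipse$semi_axes[1])^2 + (v / ellipse$semi_axes[2])^2 <= 1
}
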