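#' Anchor names of the dorsal-profile curve, in tail-to-face order
#' @return Character vector of the 8 anatomical anchor names.
#' @export
anchor_names <- function() {
  c("tail_base", "lumbosacral", "L1", "T10", "atlantooccipital",
    "temporomandibular", "eye_canthus", "facial_crest_end")
}

#' Intermediate semilandmark counts between consecutive anchors
#'
#' Three semilandmarks are inserted between the tail base and the
#' lumbosacral joint, two between the lumbosacral joint and L1, six
#' between L1 and T10, and eleven between T10 and the atlantooccipital
#' joint; the four head anchors are consecutive. 8 anchors + 22
#' intermediates = 30 curve points.
#'
#' @return Integer vector of length 7 (one per inter-anchor run).
#' @export
insert_counts <- function() c(3L, 2L, 6L, 11L, 0L, 0L, 0L)

#' Canonical indices of the 8 anchors along the 30-point curve
#' @return Named integer vector (1-based curve indices).
#' @export
anchor_indices <- function() {
  idx <- integer(8)
  idx[1] <- 1L
  k <- insert_counts()
  for (i in 2:8) idx[i] <- idx[i - 1] + k[i - 1] + 1L
  names(idx) <- anchor_names()
  idx  # 1, 5, 8, 15, 27, 28, 29, 30
}

#' Construct an anchor set
#'
#' @param anchors Numeric 8 x 2 matrix of (x, y) anchor positions in
#'   tail-to-face order ([anchor_names()]), or a named list of length-2
#'   vectors.
#' @return Object of class `anchor_set`: the 8 x 2 matrix with anchor row
#'   names.
#' @export
anchor_set <- function(anchors) {
  if (is.list(anchors)) anchors <- do.call(rbind, anchors[anchor_names()])
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 8L || ncol(anchors) != 2L)
    stop("`anchors` must be an 8 x 2 matrix in tail-to-face order")
  if (!all(is.finite(anchors))) stop("anchor coordinates must be finite")
  d <- sqrt(rowSums(diff(anchors)^2))
  if (any(d < .Machine$double.eps^0.5))
    stop("coincident consecutive anchors at run ",
         which(d < .Machine$double.eps^0.5)[1])
  dimnames(anchors) <- list(anchor_names(), c("x", "y"))
  structure(anchors, class = c("anchor_set", "matrix", "array"))
}

#' Build the 30-point dorsal-profile curve from 8 anatomical anchors
#'
#' Fits a chord-length-parameterized natural cubic spline through the
#' anchor polyline and places each run of intermediate semilandmarks at
#' equal arc length between its flanking anchors (counts per
#' [insert_counts()]). Anchors are pinned bit-exactly at their canonical
#' curve indices ([anchor_indices()]). The construction is equivariant
#' under rigid motion of the anchors.
#'
#' @param anchors An [anchor_set()] (or 8 x 2 matrix in tail-to-face
#'   order).
#' @param id,lunging_aid,time,individual Classifiers forwarded to
#'   [landmark_config()]; default ID `"A001"`.
#' @return A [landmark_config()] with 30 ordered points.
#' @export
build_curve_landmarks <- function(anchors, id = "A001", lunging_aid = NULL,
                                  time = NULL, individual = NULL) {
  if (!inherits(anchors, "anchor_set")) anchors <- anchor_set(anchors)
  pts <- curve_points_from_anchors(unclass(anchors))
  if (!is.null(lunging_aid)) id <- NULL
  landmark_config(pts, id = id, lunging_aid = lunging_aid, time = time,
                  individual = individual)
}

# Spline machinery shared by build_curve_landmarks and the synthetic
# template: returns the raw 30 x 2 matrix.
curve_points_from_anchors <- function(A) {
  chord <- sqrt(rowSums(diff(A)^2))
  t_anchor <- c(0, cumsum(chord))
  fx <- stats::splinefun(t_anchor, A[, 1], method = "natural")
  fy <- stats::splinefun(t_anchor, A[, 2], method = "natural")
  idx <- anchor_indices()
  counts <- insert_counts()
  pts <- matrix(NA_real_, N_LANDMARKS, 2L)
  pts[idx, ] <- A
  for (run in seq_len(7L)) {
    k <- counts[run]
    if (k == 0L) next
    t0 <- t_anchor[run]; t1 <- t_anchor[run + 1L]
    # arc length along the spline segment, densely sampled
    tt <- seq(t0, t1, length.out = 512L)
    seg <- cbind(fx(tt), fy(tt))
    s <- c(0, cumsum(sqrt(rowSums(diff(seg)^2))))
    targets <- s[length(s)] * seq_len(k) / (k + 1L)
    t_mid <- stats::approx(s, tt, xout = targets, ties = "ordered")$y
    pts[idx[run] + seq_len(k), ] <- cbind(fx(t_mid), fy(t_mid))
  }
  pts
}

#' Interior angle at a vertex, in degrees
#'
#' The goniometric head/neck angle check: angle between the arms
#' `vertex -> p_a` and `vertex -> p_b`, in `[0, 180]` degrees.
#'
#' @param p_a,vertex,p_b Length-2 numeric (x, y) points.
#' @return Angle in degrees.
#' @examples
#' compute_angle(c(1, 0), c(0, 0), c(0, 1))   # 90
#' compute_angle(c(1, 0), c(0, 0), c(-1, 0))  # 180
#' @export
compute_angle <- function(p_a, vertex, p_b) {
  u <- as.numeric(p_a) - as.numeric(vertex)
  v <- as.numeric(p_b) - as.numeric(vertex)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length arm: points must differ from the vertex")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Target head/neck-angle windows
#'
#' Open HNA (freely moving head or chambon): 110-115 degrees; closed HNA
#' (rubber band or triangle side reins): 85-90 degrees.
#'
#' @param posture `"open"` or `"closed"`.
#' @return Numeric length-2 `c(lo, hi)` window in degrees.
#' @export
hna_window <- function(posture = c("open", "closed")) {
  posture <- match.arg(posture)
  if (posture == "open") c(110, 115) else c(85, 90)
}
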