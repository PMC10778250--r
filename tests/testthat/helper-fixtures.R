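# shared fixtures built in code

# a valid random 30-point configuration around the dorsal-profile template
random_config <- function(seed = 1, noise_sd = 5) {
  set.seed(seed)
  pts <- build_curve_landmarks(template_anchors())$points +
    matrix(rnorm(60, 0, noise_sd), 30, 2)
  landmark_config(pts, id = "A001")
}

# a small synthetic dataset (full study design unless scaled down)
tiny_dataset <- function(seed = 1) generate_landmark_dataset(seed = seed)

# apply a random similarity transform (rotation + scale + translation)
similarity_transform <- function(pts, theta, scale, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(pts %*% t(R) * scale, 2, shift, "+")
}

# rotate the rows of a k x 2 matrix by the angle aligning `from` to `to`
rotate_onto <- function(pts, from, to) {
  zf <- complex(real = from[, 1], imaginary = from[, 2])
  zt <- complex(real = to[, 1], imaginary = to[, 2])
  s <- sum(zt * Conj(zf))
  rot <- s / Mod(s)
  z <- complex(real = pts[, 1], imaginary = pts[, 2]) * rot
  cbind(Re(z), Im(z))
}
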