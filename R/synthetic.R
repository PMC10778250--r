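#' The study design
#'
#' 13 horses, four lunging conditions (FMH, CH, RB, TRs), two imaging
#' occasions (before/after lunging): 104 occasions in total. Five
#' visible-light frames and two infrared frames were captured per
#' occasion, one of each selected.
#'
#' @param n_horses Number of horses (default 13).
#' @return List with `n_horses`, `conditions`, `times`,
#'   `frames_per_occasion_visible`, `frames_per_occasion_infrared`,
#'   `selected_per_occasion`, `occasions`.
#' @export
study_design <- function(n_horses = 13L) {
  conditions <- unname(LUNGING_AIDS)
  occasions <- n_horses * length(conditions) * 2L
  list(n_horses = as.integer(n_horses), conditions = conditions,
       times = c(0L, 1L), frames_per_occasion_visible = 5L,
       frames_per_occasion_infrared = 2L, selected_per_occasion = 1L,
       occasions = occasions)
}

#' Imaging bookkeeping counts
#'
#' Captured frames = occasions x frames per occasion; selected = one per
#' occasion. For the default design: 520 visible captured / 104 selected,
#' 208 infrared captured / 104 selected.
#'
#' @param design A [study_design()].
#' @return data.frame with modality, captured, selected.
#' @export
imaging_bookkeeping <- function(design = study_design()) {
  occ <- design$occasions
  data.frame(
    modality = c("visible", "infrared"),
    captured = c(occ * design$frames_per_occasion_visible,
                 occ * design$frames_per_occasion_infrared),
    selected = rep(occ * design$selected_per_occasion, 2L),
    stringsAsFactors = FALSE)
}

#' Cohort demographics fixture
#'
#' The 13-horse demographics table shipped with the package (sex, breed,
#' age, body condition score, height, lameness score, training background
#' and current training): 8 geldings and 5 mares, 8 Polish Halfbred and 5
#' Malopolska horses, all lameness-free.
#'
#' @return data.frame with 13 rows.
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "cohort_demographics.csv",
                      package = "equilunge", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Template dorsal-profile anchors
#'
#' A fixed, versioned dorsal-profile polyline (image-pixel units, y up,
#' tail at the left): hindquarter and back anchors at plausible positions
#' for a horse framed in a 968 x 709 raster, with the head built at a
#' requested head/neck angle (HNA). The HNA is the interior angle at the
#' atlantooccipital joint between the arms to T10 and to the
#' temporomandibular joint, so `compute_angle()` on the returned anchors
#' recovers `hna_deg` exactly.
#'
#' @param hna_deg Head/neck angle in degrees; the open-posture default
#'   112.5 sits mid-window of the 110-115 target, the closed window being
#'   85-90.
#' @return An [anchor_set()].
#' @export
template_anchors <- function(hna_deg = 112.5) {
  ao <- c(780, 560)
  t10 <- c(540, 400)
  back_dir <- atan2(t10[2] - ao[2], t10[1] - ao[1])
  th <- back_dir + hna_deg * pi / 180
  u <- function(a) c(cos(a), sin(a))
  tmj <- ao + 62 * u(th)
  eye <- tmj + 34 * u(th + 55 * pi / 180)
  crest <- eye + 30 * u(th + 5 * pi / 180)
  anchor_set(rbind(tail_base = c(120, 360), lumbosacral = c(240, 400),
                   L1 = c(370, 410), T10 = t10, atlantooccipital = ao,
                   temporomandibular = tmj, eye_canthus = eye,
                   facial_crest_end = crest))
}

#' Condition-specific posture displacement fields
#'
#' Signed vertical landmark offsets applied after lunging, in units of
#' the landmark-noise SD: FMH raises the atlantooccipital joint and the
#' tail base and lowers the mid-back; CH leaves posture unchanged; RB
#' raises the mid-back; TRs mirrors FMH (mid-back up, atlantooccipital
#' and tail base down). Each peak has magnitude `peak_sd` (default 2
#' noise-SD) and tapers over neighboring landmark indices with a Gaussian
#' bump of width `taper` indices.
#'
#' @param peak_sd Peak displacement in noise-SD units.
#' @param taper Bump width in landmark indices.
#' @return Object of class `posture_effect_spec`: a list of length-30
#'   numeric vectors named FMH, CH, RB, TRs.
#' @export
posture_effect_spec <- function(peak_sd = 2, taper = 2) {
  bump <- function(center, amp) {
    amp * exp(-((seq_len(N_LANDMARKS) - center)^2) / (2 * taper^2))
  }
  ao <- unname(anchor_indices()["atlantooccipital"])  # 27
  midback <- 14L   # middle of the back region (indices 9-19)
  tail <- 1L
  fields <- list(
    FMH = bump(ao, peak_sd) + bump(midback, -peak_sd) + bump(tail, peak_sd),
    CH = rep(0, N_LANDMARKS),
    RB = bump(midback, peak_sd),
    TRs = bump(ao, -peak_sd) + bump(midback, peak_sd) + bump(tail, -peak_sd))
  structure(fields, class = "posture_effect_spec")
}

#' Generate a synthetic landmark dataset
#'
#' Emulates the study's 104 selected visible-light observations: each
#' horse gets a base dorsal-profile template (the fixed
#' [template_anchors()] curve under a small random size and shape
#' perturbation); before-lunging configurations add isotropic landmark
#' noise; after-lunging configurations additionally receive the
#' condition's vertical displacement field ([posture_effect_spec()])
#' scaled by `noise_sd`. ID codes follow the study scheme (condition A-D,
#' time 0/1, individuals 1-52: 13 per condition).
#'
#' @param design A [study_design()].
#' @param effect A [posture_effect_spec()].
#' @param noise_sd Isotropic landmark noise SD in pixels (default 5, a
#'   realistic digitization-plus-stance scatter for ~900 px profiles).
#' @param size_sd SD of the per-horse log size factor (default 0.04).
#' @param shape_jitter_sd SD of the per-horse landmark-wise template
#'   perturbation in pixels (default 0.5, small relative to `noise_sd`:
#'   individual conformation differences are mostly size, which
#'   Procrustes analysis removes).
#' @param seed Integer seed; the only source of randomness.
#' @return A [landmark_dataset()] of `4 * n_horses * 2` configurations
#'   with attributes `effect_fields` and `noise_sd`.
#' @export
generate_landmark_dataset <- function(design = study_design(),
                                      effect = posture_effect_spec(),
                                      noise_sd = 5, size_sd = 0.04,
                                      shape_jitter_sd = 0.5, seed = 1L) {
  stopifnot(inherits(effect, "posture_effect_spec"))
  if (4L * design$n_horses > 52L)
    stop("individual codes only span 01-52: at most 13 horses")
  set.seed(seed)
  template <- curve_points_from_anchors(unclass(template_anchors()))
  configs <- list()
  for (ci in seq_along(design$conditions)) {
    cond <- design$conditions[ci]
    for (h in seq_len(design$n_horses)) {
      individual <- (ci - 1L) * design$n_horses + h
      size_f <- exp(stats::rnorm(1, 0, size_sd))
      jitter <- matrix(stats::rnorm(2L * N_LANDMARKS, 0, shape_jitter_sd),
                       N_LANDMARKS, 2L)
      base <- template + jitter
      cen <- colMeans(base)
      base <- sweep(sweep(base, 2L, cen) * size_f, 2L, cen, "+")
      for (tm in design$times) {
        pts <- base
        if (tm == 1L)
          pts[, 2L] <- pts[, 2L] + effect[[cond]] * noise_sd
        pts <- pts + matrix(stats::rnorm(2L * N_LANDMARKS, 0, noise_sd),
                            N_LANDMARKS, 2L)
        configs[[length(configs) + 1L]] <-
          landmark_config(pts, lunging_aid = cond, time = tm,
                          individual = individual)
      }
    }
  }
  ds <- landmark_dataset(configs)
  attr(ds, "effect_fields") <- effect
  attr(ds, "noise_sd") <- noise_sd
  ds
}

#' Condition-specific thermal bin-fraction targets
#'
#' Target shares of the body surface in each of the five temperature bins
#' before lunging (common to all conditions: mass concentrated in the two
#' coolest bins, none in the hottest) and after lunging per condition,
#' chosen to emulate the reported qualitative orderings: FMH moves mass
#' into bins 3-4; CH concentrates in 3-4 with little remaining in bin 1;
#' RB spreads over bins 3-5; TRs is dominated by bins 4-5 and shows the
#' largest bin-5 share.
#'
#' @param noise_sd SD of the per-image jitter applied to the target
#'   fractions before renormalization (default 0.02).
#' @return Object of class `thermal_profile_spec`.
#' @export
thermal_profile_spec <- function(noise_sd = 0.02) {
  spec <- list(
    before = c(0.35, 0.35, 0.18, 0.12, 0.00),
    after = list(
      FMH = c(0.115, 0.115, 0.35, 0.32, 0.10),
      CH  = c(0.05, 0.13, 0.30, 0.38, 0.14),
      RB  = c(0.09, 0.11, 0.26, 0.27, 0.27),
      TRs = c(0.05, 0.13, 0.15, 0.33, 0.34)),
    noise_sd = noise_sd)
  stopifnot(abs(sum(spec$before) - 1) < 1e-9,
            all(vapply(spec$after, sum, numeric(1)) - 1 < 1e-9))
  structure(spec, class = "thermal_profile_spec")
}

# Horse-silhouette mask: body ellipse, neck wedge, head, four legs.
# Coordinates normalized to [0,1] x [0,1], x left-to-right (tail to head),
# y bottom-to-top; returned as an h x w logical matrix in raster order.
.horse_silhouette <- function(width, height) {
  xs <- (seq_len(width) - 0.5) / width
  ys <- (seq_len(height) - 0.5) / height
  X <- matrix(xs, height, width, byrow = TRUE)
  Y <- matrix(rev(ys), height, width)  # raster row 1 = top
  inside <- ((X - 0.42)^2 / 0.30^2 + (Y - 0.55)^2 / 0.16^2) <= 1  # trunk
  # neck: widening band from withers (0.62, 0.62) to poll (0.80, 0.82)
  neck_t <- pmin(1, pmax(0, ((X - 0.62) * 0.18 + (Y - 0.62) * 0.20) / 0.0724))
  neck_c_x <- 0.62 + 0.18 * neck_t
  neck_c_y <- 0.62 + 0.20 * neck_t
  neck_w <- 0.085 - 0.035 * neck_t
  inside <- inside | (((X - neck_c_x)^2 + (Y - neck_c_y)^2) <= neck_w^2)
  inside <- inside | (((X - 0.84)^2 / 0.07^2 + (Y - 0.80)^2 / 0.055^2) <= 1)  # head
  for (leg_x in c(0.22, 0.32, 0.52, 0.62))  # legs to ground
    inside <- inside | (abs(X - leg_x) <= 0.025 & Y >= 0.10 & Y <= 0.48)
  inside
}

#' Generate a synthetic thermal scene
#'
#' Builds a horse-silhouette surface on a black background and draws
#' per-pixel temperatures so that the realized bin fractions match the
#' spec's target for the requested condition and time up to per-image
#' jitter and pixel quantization. Temperatures are laid out along a
#' smoothed tail-to-head gradient, placing the coolest bins on the
#' hindquarter and the warmest on the cranial back and neck. The exact
#' realized fractions are returned as ground truth.
#'
#' @param spec A [thermal_profile_spec()].
#' @param condition One of `"FMH"`, `"CH"`, `"RB"`, `"TRs"`.
#' @param time 0 (before lunging) or 1 (after).
#' @param seed Integer seed.
#' @param width,height Raster size in pixels; the study rasters are
#'   968 x 709, the default here is the 4x-downscaled 242 x 177 for fast
#'   simulation.
#' @return List with `scene` (a [thermal_scene()]), `fractions` (realized
#'   per-bin fractions, summing to 1), `counts` (per-bin pixel counts).
#' @export
generate_thermal_scene <- function(spec = thermal_profile_spec(),
                                   condition = "FMH", time = 0L,
                                   seed = 1L, width = 242L, height = 177L) {
  stopifnot(inherits(spec, "thermal_profile_spec"))
  if (!condition %in% names(spec$after)) stop("unknown condition ", condition)
  target <- if (time == 0L) spec$before else spec$after[[condition]]
  if (any(target < 0)) stop("infeasible target: negative bin mass")
  set.seed(seed)
  mask <- .horse_silhouette(width, height)
  S <- sum(mask)
  # per-image jitter on the target fractions, then largest-remainder
  # apportionment of the S surface pixels
  f <- pmax(0, target + stats::rnorm(5, 0, spec$noise_sd) * (target > 0))
  f <- f / sum(f)
  raw <- f * S
  counts <- floor(raw)
  short <- S - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  # spatial layout: cool -> warm along tail-to-head score with smooth noise
  idx <- which(mask)
  col_of <- (idx - 1L) %/% height + 1L
  row_of <- (idx - 1L) %% height + 1L
  score <- col_of / width + 0.25 * (1 - row_of / height) +
    0.15 * stats::runif(length(idx))
  ord <- idx[order(score)]
  temps <- matrix(NA_real_, height, width)
  bins <- pcp_bins()
  pos <- 0L
  for (b in 1:5) {
    if (counts[b] == 0L) next
    px <- ord[pos + seq_len(counts[b])]
    hi <- if (b == 5L) bins$t_hi[b] else bins$t_hi[b] - 1e-6
    temps[px] <- stats::runif(counts[b], bins$t_lo[b], hi)
    pos <- pos + counts[b]
  }
  list(scene = thermal_scene(temps, mask), fractions = counts / S,
       counts = as.integer(counts))
}
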