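#' Run the posture analysis pipeline
#'
#' End-to-end geometric-morphometric analysis of a landmark dataset,
#' mirroring the study's report structure: a Procrustes fit and PCA of
#' the whole dataset with shape and centroid-size ANOVA for both
#' classifiers (lunging aid, time); a fresh Procrustes fit per time
#' subset testing the lunging-aid effect; and a fresh fit per condition
#' subset testing the time effect. Shape degrees of freedom follow the
#' design only: `(g-1) * 56` for 30 2-D landmarks.
#'
#' @param dataset A [landmark_dataset()] with populated classifiers.
#' @param p_method Passed to [procrustes_anova_shape()].
#' @param n_permutations,seed Permutation options when
#'   `p_method = "permutation"`.
#' @return Object of class `posture_report`: `pca_summary`, `scores`
#'   (with classifier columns), `anova` (long table: analysis, subset,
#'   response, effect, SS, MS, df, F, p), `consensus_by_la`,
#'   `consensus_by_time`, `fit` (whole-dataset [gpa()] fit), `skipped`.
#' @export
run_posture_pipeline <- function(dataset, p_method = "parametric",
                                 n_permutations = 10000L, seed = NULL) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  meta <- dataset$meta
  skipped <- character(0)
  rows <- list()
  add_rows <- function(analysis, subset, fit, labels, effect_name) {
    sh <- procrustes_anova_shape(fit, labels, p_method = p_method,
                                 n_permutations = n_permutations, seed = seed)
    sz <- anova_centroid_size(fit$centroid_sizes, labels)
    rbind(
      data.frame(analysis = analysis, subset = subset, response = "shape",
                 effect = effect_name, SS = sh$SS, MS = sh$MS, df = sh$df,
                 F = sh$F, p = sh$p, stringsAsFactors = FALSE),
      data.frame(analysis = analysis, subset = subset,
                 response = "centroid size", effect = effect_name,
                 SS = sz$SS, MS = sz$MS, df = sz$df, F = sz$F, p = sz$p,
                 stringsAsFactors = FALSE))
  }
  # whole dataset: both classifiers
  fit <- gpa(dataset)
  pca_res <- pca(fit)
  rows[[1]] <- add_rows("whole", "all", fit, meta$lunging_aid, "LAs")
  rows[[2]] <- add_rows("whole", "all", fit, meta$time, "time")
  # by-time subsets: lunging-aid effect within each
  for (tm in c(0L, 1L)) {
    idx <- meta$time == tm
    if (sum(idx) < 2L) {
      skipped <- c(skipped, paste0("time subset ", tm, ": <2 specimens"))
      warning("skipping time subset ", tm, ": fewer than 2 specimens")
      next
    }
    sub_fit <- gpa(subset_dataset(dataset, idx))
    rows[[length(rows) + 1L]] <-
      add_rows("by_time", paste0("subset ", tm), sub_fit,
               meta$lunging_aid[idx], "LAs")
  }
  # by-condition subsets: time effect within each
  for (cond in unname(LUNGING_AIDS)) {
    idx <- meta$lunging_aid == cond
    if (sum(idx) < 2L) {
      skipped <- c(skipped, paste0("condition subset ", cond, ": <2 specimens"))
      warning("skipping condition subset ", cond, ": fewer than 2 specimens")
      next
    }
    sub_fit <- gpa(subset_dataset(dataset, idx))
    rows[[length(rows) + 1L]] <-
      add_rows("by_condition", paste0("subset ", cond), sub_fit,
               meta$time[idx], "time")
  }
  scores <- data.frame(meta, pca_res$scores[, seq_len(min(3L, ncol(pca_res$scores))),
                                            drop = FALSE])
  names(scores)[-(1:4)] <- paste0("PC", seq_len(ncol(scores) - 4L))
  structure(list(pca_summary = pc_summary(pca_res), scores = scores,
                 anova = do.call(rbind, rows),
                 consensus_by_la = consensus_by_class(fit, meta$lunging_aid),
                 consensus_by_time = consensus_by_class(fit, meta$time),
                 fit = fit, pca = pca_res, skipped = skipped),
            class = "posture_report")
}

#' Run the thermal analysis pipeline
#'
#' Pixel-Counting-Protocol statistics over a set of per-image surface
#' profiles: within every condition-by-time subset, the bin percentages
#' are compared between the five temperature ranges; within every range,
#' they are compared between the four condition subsets, before and after
#' lunging separately. All comparisons are Kruskal-Wallis followed by
#' Dunn's test (Bonferroni within family), with compact-letter displays.
#'
#' @param profiles Long data.frame with one row per image per bin:
#'   columns `condition`, `time`, `image_id`, `bin` (1-5), `percent`.
#' @return Object of class `thermal_report`: `profiles` (the input),
#'   `between_ranges` (per-subset KW results and letters),
#'   `between_subsets` (per-time, per-bin KW results and letters),
#'   `summary` (per subset and bin box descriptives).
#' @export
run_thermal_pipeline <- function(profiles) {
  needed <- c("condition", "time", "image_id", "bin", "percent")
  if (!all(needed %in% names(profiles)))
    stop("`profiles` must have columns ", paste(needed, collapse = ", "))
  subsets <- unique(profiles[, c("condition", "time")])
  subsets <- subsets[order(match(subsets$condition, unname(LUNGING_AIDS)),
                           subsets$time), ]
  between_ranges <- list()
  summary_rows <- list()
  for (r in seq_len(nrow(subsets))) {
    cond <- subsets$condition[r]; tm <- subsets$time[r]
    sub <- profiles[profiles$condition == cond & profiles$time == tm, ]
    if (!nrow(sub)) stop("empty subset ", cond, " time ", tm)
    groups <- split(sub$percent, sub$bin)
    names(groups) <- paste0("bin", names(groups))
    kw <- kruskal_wallis(groups)
    letters_cld <- compact_letters(kw$pairwise, names(groups))
    key <- paste0(cond, "_", tm)
    between_ranges[[key]] <- list(condition = cond, time = tm, kw = kw,
                                  letters = letters_cld)
    for (b in names(groups)) {
      bx <- describe_box(groups[[b]])
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(condition = cond, time = tm, bin = b,
                   n = length(groups[[b]]), median = bx$median,
                   lower_quartile = bx$lower_quartile,
                   upper_quartile = bx$upper_quartile,
                   minimum = bx$minimum, maximum = bx$maximum,
                   letter = unname(letters_cld[b]),
                   stringsAsFactors = FALSE)
    }
  }
  between_subsets <- list()
  for (tm in sort(unique(profiles$time))) {
    for (b in sort(unique(profiles$bin))) {
      sub <- profiles[profiles$time == tm & profiles$bin == b, ]
      groups <- split(sub$percent, sub$condition)
      groups <- groups[order(match(names(groups), unname(LUNGING_AIDS)))]
      if (length(groups) < 2L) next
      if (length(unique(unlist(groups))) == 1L) next  # degenerate (e.g. all-zero bin)
      kw <- kruskal_wallis(groups)
      between_subsets[[paste0("time", tm, "_bin", b)]] <-
        list(time = tm, bin = b, kw = kw,
             letters = compact_letters(kw$pairwise, names(groups)))
    }
  }
  structure(list(profiles = profiles,
                 between_ranges = between_ranges,
                 between_subsets = between_subsets,
                 summary = do.call(rbind, summary_rows)),
            class = "thermal_report")
}

#' Generate synthetic data and run both pipelines
#'
#' The one-call demonstration: generates the 104-configuration landmark
#' dataset and one thermal scene per infrared occasion from a single
#' seed, runs the posture and thermal pipelines, and (optionally) writes
#' the report tables with a provenance block. Bit-reproducible given the
#' seed.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory for CSV tables; `NULL` (default)
#'   writes nothing.
#' @param design A [study_design()].
#' @param effect A [posture_effect_spec()].
#' @param thermal_spec A [thermal_profile_spec()].
#' @param width,height Thermal raster size (default 242 x 177).
#' @param p_method Passed to the posture pipeline.
#' @return List with `posture` (a `posture_report`), `thermal` (a
#'   `thermal_report`), `landmarks` (the dataset), `provenance`.
#' @export
end_to_end <- function(seed = 1L, out_dir = NULL, design = study_design(),
                       effect = posture_effect_spec(),
                       thermal_spec = thermal_profile_spec(),
                       width = 242L, height = 177L,
                       p_method = "parametric") {
  landmarks <- generate_landmark_dataset(design = design, effect = effect,
                                         seed = seed)
  posture <- run_posture_pipeline(landmarks, p_method = p_method)
  prof_rows <- list()
  occ <- 0L
  for (ci in seq_along(design$conditions)) {
    cond <- design$conditions[ci]
    for (tm in design$times) {
      for (h in seq_len(design$n_horses)) {
        occ <- occ + 1L
        gen <- generate_thermal_scene(thermal_spec, cond, tm,
                                      seed = seed + occ,
                                      width = width, height = height)
        prof <- surface_profile(render_thermogram(gen$scene))
        prof_rows[[occ]] <- data.frame(
          condition = cond, time = tm,
          image_id = make_id_code(cond, tm, (ci - 1L) * design$n_horses + h),
          bin = 1:5, percent = prof$percentages, stringsAsFactors = FALSE)
      }
    }
  }
  profiles <- do.call(rbind, prof_rows)
  thermal <- run_thermal_pipeline(profiles)
  provenance <- data.frame(
    key = c("seed", "package_version", "n_landmark_configs",
            "n_thermal_images", "raster", "p_method"),
    value = c(seed, as.character(utils::packageVersion("equilunge")),
              n_specimens(landmarks), occ, paste0(width, "x", height),
              p_method),
    stringsAsFactors = FALSE)
  result <- list(posture = posture, thermal = thermal,
                 landmarks = landmarks, provenance = provenance)
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' Write the report tables of an [end_to_end()] run
#' @param result An [end_to_end()] result.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  w(result$posture$anova, "posture_anova.csv")
  w(result$posture$pca_summary, "pc_summary.csv")
  w(result$posture$scores, "pc_scores.csv")
  w(result$thermal$profiles, "thermal_profiles.csv")
  w(result$thermal$summary, "thermal_summary.csv")
  w(result$provenance, "provenance.csv")
  invisible(out_dir)
}
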