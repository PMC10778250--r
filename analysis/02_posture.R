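#!/usr/bin/env Rscript
# Step 2: the posture analysis.
#
# Reads the simulated TPS file, superimposes all dorsal profiles with GPA,
# summarizes shape variation with PCA, and tests the lunging-aid and time
# classifiers with Procrustes ANOVA (shape) and one-way ANOVA (centroid
# size) on the whole dataset, the two time subsets, and the four condition
# subsets. Writes the report tables and wireframe/ellipse figures.

library(equilunge)

in_tps <- "results/simulated/landmarks.tps"
out_dir <- "results/posture"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(in_tps)) stop("run analysis/01_simulate.R first")

landmarks <- read_tps(in_tps)
message("Read ", n_specimens(landmarks), " configurations")

report <- run_posture_pipeline(landmarks)
utils::write.csv(report$anova, file.path(out_dir, "anova_tables.csv"),
                 row.names = FALSE)
utils::write.csv(report$pca_summary, file.path(out_dir, "pc_summary.csv"),
                 row.names = FALSE)
utils::write.csv(report$scores, file.path(out_dir, "pc_scores.csv"),
                 row.names = FALSE)

p3 <- report$pca_summary[1:3, ]
message(sprintf("PC1-PC3 explain %.1f%% of shape variance (%.1f, %.1f, %.1f)",
                p3$cum_pct[3], p3$pct[1], p3$pct[2], p3$pct[3]))
sh <- report$anova[report$anova$response == "shape", ]
message("Shape effects (Goodall F):")
for (r in seq_len(nrow(sh)))
  message(sprintf("  %-12s %-10s %-5s df=%3d  F=%6.2f  p=%.4g",
                  sh$analysis[r], sh$subset[r], sh$effect[r], sh$df[r],
                  sh$F[r], sh$p[r]))

grDevices::png(file.path(out_dir, "pc_wireframes.png"), 1200, 400, res = 110)
graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
for (j in 1:3) {
  mag <- 3 * stats::sd(report$pca$scores[, j])
  plot_wireframe(report$pca$consensus, pc_deformation(report$pca, j, mag),
                 main = sprintf("PC%d (%.1f%%)", j, report$pca_summary$pct[j]))
}
grDevices::dev.off()

grDevices::png(file.path(out_dir, "pc_scores_ellipses.png"), 1000, 500,
               res = 110)
graphics::par(mfrow = c(1, 2))
plot_scores_ellipses(report$pca$scores[, 1:2], landmarks$meta$lunging_aid,
                     main = "Grouped by lunging aid")
plot_scores_ellipses(report$pca$scores[, 1:2], landmarks$meta$time,
                     main = "Grouped by time")
grDevices::dev.off()

grDevices::png(file.path(out_dir, "consensus_by_condition.png"), 1200, 300,
               res = 110)
graphics::par(mfrow = c(1, 4), mar = c(1, 1, 2, 1))
for (cond in c("FMH", "CH", "RB", "TRs")) {
  idx <- landmarks$meta$lunging_aid == cond
  sub_fit <- gpa(subset_dataset(landmarks, idx))
  cons <- consensus_by_class(sub_fit, landmarks$meta$time[idx])
  plot_wireframe(cons$`0`, cons$`1`, main = paste(cond, "before vs after"))
}
grDevices::dev.off()

message("Done: posture tables and figures under ", out_dir)
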