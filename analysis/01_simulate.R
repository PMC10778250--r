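#!/usr/bin/env Rscript
# Step 1: simulate the study's raw data.
#
# Generates the 104 selected visible-light observations as a TPS landmark
# file (13 horses x 4 lunging conditions x before/after, 30-point dorsal
# profiles) and one pseudocolor thermogram per infrared occasion (PNG,
# with the per-scene ground-truth bin fractions). Everything flows from
# one seed; rerunning reproduces the same files.

library(equilunge)

seed <- 1L
out_dir <- "results/simulated"
dir.create(file.path(out_dir, "thermograms"), recursive = TRUE,
           showWarnings = FALSE)

message("Generating the 104-observation landmark dataset (seed ", seed, ")")
landmarks <- generate_landmark_dataset(seed = seed)
write_tps(landmarks, file.path(out_dir, "landmarks.tps"))
utils::write.csv(dataset_to_df(landmarks),
                 file.path(out_dir, "landmarks_long.csv"), row.names = FALSE)
message("  -> ", n_specimens(landmarks), " configurations written")

message("Generating one thermal scene per infrared occasion")
design <- study_design()
spec <- thermal_profile_spec()
truth <- list()
occ <- 0L
for (ci in seq_along(design$conditions)) {
  cond <- design$conditions[ci]
  for (tm in design$times) {
    for (h in seq_len(design$n_horses)) {
      occ <- occ + 1L
      id <- make_id_code(cond, tm, (ci - 1L) * design$n_horses + h)
      gen <- generate_thermal_scene(spec, cond, tm, seed = seed + occ)
      img <- render_thermogram(gen$scene)
      write_thermogram_png(img, file.path(out_dir, "thermograms",
                                          paste0(id, ".png")))
      truth[[occ]] <- data.frame(image_id = id, condition = cond, time = tm,
                                 bin = 1:5, true_count = gen$counts,
                                 true_fraction = gen$fractions)
    }
  }
}
utils::write.csv(do.call(rbind, truth),
                 file.path(out_dir, "thermogram_ground_truth.csv"),
                 row.names = FALSE)
message("  -> ", occ, " thermograms written (242 x 177 px)")

bk <- imaging_bookkeeping(design)
print(bk)
message("Done: study inputs under ", out_dir)
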