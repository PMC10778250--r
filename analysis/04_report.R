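#!/usr/bin/env Rscript
# Step 4: cohort descriptives and the combined provenance-stamped report.
#
# Recomputes the cohort summary from the bundled demographics table,
# checks the imaging bookkeeping, and bundles the posture and thermal
# outputs of steps 2-3 into results/report/.

library(equilunge)

out_dir <- "results/report"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- cohort_fixture()
st <- descriptive_cohort(cohort)
utils::write.csv(st, file.path(out_dir, "cohort_descriptives.csv"),
                 row.names = FALSE)
message("Cohort (n = ", nrow(cohort), "): ",
        sprintf("age %.2f +/- %.2f y, height %.2f +/- %.2f cm, BCS %.2f +/- %.2f",
                st$mean[1], st$sd[1], st$mean[2], st$sd[2], st$mean[3],
                st$sd[3]))
for (v in c("age_years", "height_cm", "bcs")) {
  nc <- normality_check(cohort[[v]])
  message(sprintf("  Shapiro-Wilk %-10s W=%.3f p=%.3f", v, nc$W, nc$p))
}

bk <- imaging_bookkeeping()
utils::write.csv(bk, file.path(out_dir, "imaging_bookkeeping.csv"),
                 row.names = FALSE)

copied <- 0L
for (f in c("posture/anova_tables.csv", "posture/pc_summary.csv",
            "thermal/profile_summary.csv", "thermal/between_subset_tests.csv")) {
  src <- file.path("results", f)
  if (file.exists(src)) {
    file.copy(src, file.path(out_dir, basename(f)), overwrite = TRUE)
    copied <- copied + 1L
  }
}
message(copied, " step-2/3 tables bundled into ", out_dir)

provenance <- data.frame(
  key = c("package", "version", "r_version", "date"),
  value = c("equilunge", as.character(utils::packageVersion("equilunge")),
            paste(R.version$major, R.version$minor, sep = "."),
            format(Sys.Date())))
utils::write.csv(provenance, file.path(out_dir, "provenance.csv"),
                 row.names = FALSE)
message("Done: report under ", out_dir)
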