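# study design, synthetic landmark and thermal generators, fixtures

test_that("the generated landmark dataset mirrors the study design", {
  ds <- generate_landmark_dataset(seed = 61)
  expect_identical(n_specimens(ds), 104L)
  expect_equal(unname(table(ds$meta$lunging_aid)), rep(26L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(ds$meta$time)), c(52L, 52L), ignore_attr = TRUE)
  expect_identical(sort(unique(ds$meta$individual)), 1:52)
  # every ID code is well-formed and round-trips
  for (i in seq_len(104)) {
    dec <- parse_id_code(ds$meta$specimen_id[i])
    expect_identical(dec$lunging_aid, ds$meta$lunging_aid[i])
    expect_identical(dec$time, ds$meta$time[i])
    expect_identical(dec$individual, ds$meta$individual[i])
  }
})

test_that("the landmark generator is seed-deterministic", {
  d1 <- generate_landmark_dataset(seed = 62)
  d2 <- generate_landmark_dataset(seed = 62)
  d3 <- generate_landmark_dataset(seed = 63)
  expect_identical(d1$coords, d2$coords)
  expect_identical(d1$meta, d2$meta)
  expect_false(identical(d1$coords, d3$coords))
})

test_that("zero effect and zero noise reproduce each horse exactly", {
  ds <- generate_landmark_dataset(effect = posture_effect_spec(peak_sd = 0),
                                  noise_sd = 0, size_sd = 0,
                                  shape_jitter_sd = 0, seed = 64)
  for (ind in unique(ds$meta$individual)) {
    pair <- which(ds$meta$individual == ind)
    expect_identical(ds$coords[, , pair[1]], ds$coords[, , pair[2]])
  }
  # CH displacement field is identically zero
  expect_identical(posture_effect_spec()$CH, rep(0, 30))
})

test_that("imaging bookkeeping reproduces the captured/selected counts", {
  bk <- imaging_bookkeeping()
  expect_identical(bk$captured[bk$modality == "visible"], 520L)
  expect_identical(bk$selected[bk$modality == "visible"], 104L)
  expect_identical(bk$captured[bk$modality == "infrared"], 208L)
  expect_identical(bk$selected[bk$modality == "infrared"], 104L)
  # one frame per occasion: captured equals selected
  d1 <- study_design()
  d1$frames_per_occasion_visible <- 1L
  bk1 <- imaging_bookkeeping(d1)
  expect_identical(bk1$captured[1], bk1$selected[1])
})

test_that("the cohort fixture matches the reference demographics", {
  tab <- cohort_fixture()
  expect_identical(nrow(tab), 13L)
  expect_identical(sum(tab$sex == "G"), 8L)
  expect_identical(sum(tab$sex == "M"), 5L)
  expect_identical(sum(tab$breed == "PHB"), 8L)
  expect_identical(sum(tab$breed == "MLP"), 5L)
  expect_true(all(tab$lameness == 0))
  expect_true(all(tab$age_years >= 6 & tab$age_years <= 20))
  expect_true(all(tab$height_cm >= 146 & tab$height_cm <= 170))
})

test_that("thermal scenes realize their returned ground truth exactly", {
  for (cond in c("FMH", "CH", "RB", "TRs")) for (tm in 0:1) {
    gen <- generate_thermal_scene(condition = cond, time = tm,
                                  seed = 65 + tm, width = 121L, height = 88L)
    expect_equal(sum(gen$fractions), 1, tolerance = 1e-12)
    expect_identical(as.integer(gen$counts),
                     as.integer(temperature_bin_tally(gen$scene)))
    # full pipeline round-trip reproduces ground truth pixel-exactly
    prof <- surface_profile(render_thermogram(gen$scene))
    expect_identical(prof$counts, as.integer(gen$counts))
    expect_equal(prof$percentages, 100 * gen$fractions, tolerance = 1e-12)
  }
})

test_that("before-lunging scenes put the most mass in the two coolest bins", {
  gen <- generate_thermal_scene(condition = "RB", time = 0L, seed = 66,
                                width = 121L, height = 88L)
  f <- gen$fractions
  expect_gt(f[1] + f[2], 0.5)
  expect_true(all(f[1:2] > f[3]))
  expect_true(all(f[3] > f[4:5]))
  # target-vs-realized differ only by jitter and quantization
  target <- thermal_profile_spec()$before
  expect_lt(max(abs(f - target)), 0.1)
})

test_that("injected displacement fields are recoverable from class consensus", {
  # the mean recovered displacement field over replicates correlates
  # > 0.9 with the injected field (per-replicate noise in a 13-per-cell
  # consensus difference is too large for the bound; in expectation the
  # recovery is essentially exact)
  field <- posture_effect_spec()$RB
  recovered <- rowMeans(vapply(1:60, function(r) {
    ds <- generate_landmark_dataset(seed = 7000 + r)
    idx <- ds$meta$lunging_aid == "RB"
    fit <- gpa(subset_dataset(ds, idx))
    cons <- consensus_by_class(fit, ds$meta$time[idx])
    cons$`1`[, 2] - cons$`0`[, 2]
  }, numeric(30)))
  expect_gt(cor(recovered, field), 0.9)
})
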