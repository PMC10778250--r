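# pseudocolor rendering, masking, CIELAB classification, surface profiles

test_that("temperature bins honor the half-open/closed edge notation", {
  expect_identical(bin_of_temperature(29), 1L)
  expect_identical(bin_of_temperature(30), 2L)   # [30, 32) opens at 30
  expect_identical(bin_of_temperature(31.999), 2L)
  expect_identical(bin_of_temperature(32), 3L)
  expect_identical(bin_of_temperature(34), 4L)
  expect_identical(bin_of_temperature(36), 5L)
  expect_identical(bin_of_temperature(38), 5L)   # top bin closed at 38
  expect_identical(bin_of_temperature(27.999), 0L)  # below range: background
  expect_identical(bin_of_temperature(41), 5L)   # clamped above range
  expect_error(bin_of_temperature(NA_real_), "finite")
})

test_that("every palette color over the range classifies to its own bin", {
  tt <- seq(28, 38, by = 0.01)
  cols <- palette_color_at(tt)
  expect_identical(classify_color(cols), bin_of_temperature(tt))
  # bin reference colors classify to their own bins by construction
  refs <- bin_reference_colors()
  expect_identical(classify_color(refs), 1:5)
})

test_that("rendering blacks out background and starts at the first stop", {
  # all-background scene
  sc <- thermal_scene(matrix(NA_real_, 4, 5),
                      mask = matrix(FALSE, 4, 5))
  img <- render_thermogram(sc)
  expect_true(all(img == 0L))
  # just below threshold -> black; at threshold -> first palette stop
  sc2 <- thermal_scene(matrix(c(27.999, 28), 1, 2))
  img2 <- render_thermogram(sc2)
  expect_identical(img2[1, 1, ], c(0L, 0L, 0L))
  first_stop <- as.integer(grDevices::col2rgb(default_palette()$hex_lo[1]))
  expect_identical(img2[1, 2, ], first_stop)
})

test_that("surface masking is exact #000000 equality", {
  img <- array(0L, dim = c(3, 4, 3))
  img[1, 1, ] <- c(1L, 1L, 1L)   # near-black still surface
  img[2, 3, ] <- c(255L, 0L, 0L)
  surf <- mask_background(img)
  expect_identical(sum(surf), 2L)
  expect_true(surf[1, 1] && surf[2, 3])
  expect_error(mask_background(array(0L, dim = c(2, 2, 3))), "empty surface")
})

test_that("color histograms count every surface pixel exactly", {
  # uniform surface: one entry with the full count
  img <- array(0L, dim = c(6, 6, 3))
  img[, , 1] <- 200L
  h <- extract_color_histogram(img)
  expect_identical(nrow(h), 1L)
  expect_identical(h$count, 36L)
  # two-color checkerboard: two equal counts
  chk <- array(0L, dim = c(4, 4, 3))
  pattern <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  chk[, , 1] <- 100L + 50L * pattern
  chk[, , 3] <- 30L
  h2 <- extract_color_histogram(chk)
  expect_identical(sort(h2$count), c(8L, 8L))
  # random raster: counts match a brute-force per-pixel tally
  set.seed(41)
  rnd <- array(sample(0:3, 5 * 7 * 3, replace = TRUE), dim = c(5, 7, 3))
  surf <- mask_background(rnd)
  h3 <- extract_color_histogram(rnd, surf)
  expect_identical(sum(h3$count), sum(surf))
  for (r in seq_len(nrow(h3))) {
    manual <- sum(rnd[, , 1] == h3$r[r] & rnd[, , 2] == h3$g[r] &
                    rnd[, , 3] == h3$b[r] & surf)
    expect_identical(h3$count[r], manual)
  }
})

test_that("sRGB to CIELAB conversion hits the reference values", {
  wh <- srgb_to_lab(c(255, 255, 255))
  expect_equal(unname(wh[1, "L"]), 100, tolerance = 1e-6)
  expect_lt(abs(wh[1, "a"]), 0.01)
  expect_lt(abs(wh[1, "b"]), 0.01)
  expect_equal(unname(srgb_to_lab(c(0, 0, 0))[1, "L"]), 0, tolerance = 1e-9)
  skip_if_not_installed("farver")
  set.seed(42)
  cols <- rbind(c(119, 119, 119),
                matrix(sample(0:255, 60, replace = TRUE), ncol = 3))
  ref <- farver::convert_colour(cols, "rgb", "lab")
  expect_lt(max(abs(srgb_to_lab(cols) - ref)), 0.01)
})

test_that("CIE76 distance is the CIELAB Euclidean metric", {
  expect_equal(delta_e76(c(50, 0, 0), c(50, 0, 0)), 0)
  expect_equal(delta_e76(c(50, 0, 0), c(60, 0, 0)), 10)
  expect_equal(delta_e76(c(50, 10, 10), c(53, 14, 22)), 13)  # 3-4-12 triple
  # metric axioms on random triples
  set.seed(43)
  for (rep in 1:50) {
    a <- c(runif(1, 0, 100), runif(2, -80, 80))
    b <- c(runif(1, 0, 100), runif(2, -80, 80))
    cc <- c(runif(1, 0, 100), runif(2, -80, 80))
    expect_equal(delta_e76(a, b), delta_e76(b, a), tolerance = 1e-12)
    expect_gte(delta_e76(a, b) + 1e-12, 0)
    expect_lte(delta_e76(a, cc), delta_e76(a, b) + delta_e76(b, cc) + 1e-12)
  }
  expect_equal(delta_e76(c(0, 0, 0), c(0, 0, 0)), 0)
})

test_that("classification refuses the background color", {
  expect_error(classify_color(c(0, 0, 0)), "background")
  expect_identical(classify_color(palette_color_at(33)), 3L)
})

test_that("surface profiles reproduce constructed bin fractions exactly", {
  # four equal quarters in bins 1-4, nothing in bin 5
  temps <- matrix(rep(c(28.5, 30.5, 32.5, 34.5), each = 25), 10, 10)
  sc <- thermal_scene(temps)
  prof <- surface_profile(render_thermogram(sc))
  expect_identical(prof$counts, c(25L, 25L, 25L, 25L, 0L))
  expect_equal(prof$percentages, c(25, 25, 25, 25, 0))
  expect_equal(sum(prof$percentages), 100, tolerance = 1e-9)
})

test_that("rendered profiles equal the direct temperature tally pixel-exactly", {
  set.seed(11)
  for (rep in 1:5) {
    temps <- matrix(runif(30 * 40, 26, 40), 30, 40)
    sc <- thermal_scene(temps)
    prof <- surface_profile(render_thermogram(sc))
    bins <- bin_of_temperature(as.vector(temps))
    direct <- vapply(1:5, function(b) sum(bins == b), integer(1))
    expect_identical(prof$counts, direct)
    expect_identical(prof$total_surface_pixels, sum(bins > 0L))
  }
})

test_that("profiles are invariant under background padding", {
  set.seed(44)
  temps <- matrix(runif(100, 29, 37), 10, 10)
  img <- render_thermogram(thermal_scene(temps))
  prof <- surface_profile(img)
  padded <- array(0L, dim = c(30, 30, 3))
  padded[11:20, 11:20, ] <- img
  prof2 <- surface_profile(padded)
  expect_identical(prof2$counts, prof$counts)
  expect_equal(prof2$percentages, prof$percentages)
})

test_that("a +2 degree shift moves each bin's mass up one bin with clamping", {
  set.seed(45)
  temps <- matrix(runif(400, 28, 38), 20, 20)
  sc <- thermal_scene(temps)
  base <- surface_profile(render_thermogram(sc))
  shifted <- surface_profile(render_thermogram(thermal_scene(temps + 2)))
  expect_identical(shifted$counts,
                   c(0L, base$counts[1:3], base$counts[4] + base$counts[5]))
})

test_that("PNG write/read round-trips thermograms losslessly", {
  set.seed(46)
  temps <- matrix(runif(200, 27, 39), 10, 20)
  img <- render_thermogram(thermal_scene(temps))
  f <- withr::local_tempfile(fileext = ".png")
  write_thermogram_png(img, f)
  back <- read_thermogram_png(f)
  expect_identical(back, img + 0L)
  expect_identical(surface_profile(back)$counts, surface_profile(img)$counts)
})

test_that("temperature CSV input round-trips into a scene", {
  temps <- matrix(c(29.5, NA, 33.2, 37.8), 2, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write.table(temps, f, sep = ",", row.names = FALSE, col.names = FALSE)
  sc <- read_temperature_csv(f)
  expect_equal(sc$temperatures, temps)
  expect_identical(sc$mask, is.finite(temps))
})

test_that("pie sectors are proportional, complete, and deterministic", {
  temps <- matrix(rep(c(28.5, 30.5, 32.5, 34.5), c(10, 20, 30, 40)), 10, 10)
  prof <- surface_profile(render_thermogram(thermal_scene(temps)))
  s1 <- profile_to_pie(prof, plot = FALSE)
  expect_equal(s1$angle_deg, 360 * prof$percentages / 100, tolerance = 1e-12)
  expect_identical(nrow(s1), 5L)           # zero-count bin keeps its slot
  expect_equal(sum(s1$angle_deg), 360, tolerance = 1e-9)
  s2 <- profile_to_pie(prof, plot = FALSE)
  expect_identical(s1, s2)
})
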