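# TPS I/O, ID codes, curve construction, angles

test_that("ID codes decode to the stated classifiers and reject bad codes", {
  expect_equal(parse_id_code("A001"),
               list(lunging_aid = "FMH", time = 0L, individual = 1L))
  expect_equal(parse_id_code("D152"),
               list(lunging_aid = "TRs", time = 1L, individual = 52L))
  expect_equal(parse_id_code("B014")$lunging_aid, "CH")
  expect_equal(parse_id_code("C027")$lunging_aid, "RB")
  expect_error(parse_id_code("E101"), "malformed")
  expect_error(parse_id_code("A201"), "malformed")
  expect_error(parse_id_code("A000"), "between 01 and 52")
  expect_error(parse_id_code("A053"), "between 01 and 52")
  expect_error(parse_id_code("A01"), "malformed")
})

test_that("encode/decode is a bijection over the full 4 x 2 x 52 code space", {
  codes <- character(0)
  for (la in unname(LUNGING_AIDS)) for (tm in 0:1) for (ind in 1:52) {
    code <- make_id_code(la, tm, ind)
    dec <- parse_id_code(code)
    expect_identical(dec, list(lunging_aid = la, time = tm, individual = ind))
    codes <- c(codes, code)
  }
  expect_length(unique(codes), 4 * 2 * 52)
})

test_that("region partition is total and disjoint over the 30 indices", {
  reg <- landmark_regions()
  expect_length(reg, 30)
  expect_equal(as.integer(table(reg)[c("hindquarter", "back", "head_neck")]),
               c(8L, 11L, 11L))
  expect_true(all(reg[1:8] == "hindquarter"))
  expect_true(all(reg[9:19] == "back"))
  expect_true(all(reg[20:30] == "head_neck"))
})

test_that("TPS files round-trip and reject malformed records", {
  ds <- generate_landmark_dataset(seed = 3)
  f1 <- withr::local_tempfile(fileext = ".tps")
  f2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(ds, f1)
  back <- read_tps(f1)
  expect_equal(n_specimens(back), 104)
  expect_identical(back$meta, ds$meta)
  expect_equal(back$coords, ds$coords, tolerance = 1e-8)
  # write -> read -> write is byte-identical
  write_tps(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # empty dataset: empty file, zero records
  fe <- withr::local_tempfile(fileext = ".tps")
  write_tps(landmark_dataset(list()), fe)
  expect_equal(n_specimens(read_tps(fe)), 0)

  # a single well-formed record
  cfg <- random_config(2)
  f3 <- withr::local_tempfile(fileext = ".tps")
  write_tps(landmark_dataset(list(cfg)), f3)
  one <- read_tps(f3)
  expect_equal(one$meta$lunging_aid, "FMH")
  expect_equal(one$meta$time, 0L)
  expect_equal(one$meta$individual, 1L)

  # comma decimal separators are a dialect error
  bad <- readLines(f3)
  bad[2] <- gsub(".", ",", bad[2], fixed = TRUE)
  fb <- withr::local_tempfile(fileext = ".tps")
  writeLines(bad, fb)
  expect_error(read_tps(fb), "comma")

  # wrong LM count
  bad2 <- readLines(f3)
  bad2[1] <- "LM=29"
  writeLines(bad2, fb)
  expect_error(read_tps(fb), "LM=")

  # missing ID key
  bad3 <- readLines(f3)
  writeLines(bad3[-32], fb)
  expect_error(read_tps(fb), "ID")

  # non-numeric coordinate, error names record and line
  bad4 <- readLines(f3)
  bad4[5] <- "12.3 oops"
  writeLines(bad4, fb)
  expect_error(read_tps(fb), "record 1 \\(line 5\\)")
})

test_that("unknown TPS keys are preserved on round-trip and CRLF accepted", {
  cfg <- random_config(4)
  cfg$extra <- c(IMAGE = "horse01.jpg", SCALE = "0.01", CURVEID = "7")
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(landmark_dataset(list(cfg)), f)
  back <- read_tps(f)
  expect_identical(back$extra[[1]],
                   c(IMAGE = "horse01.jpg", SCALE = "0.01", CURVEID = "7"))
  # CRLF line endings
  crlf <- withr::local_tempfile(fileext = ".tps")
  writeLines(readLines(f), crlf, sep = "\r\n")
  expect_equal(read_tps(crlf)$coords, back$coords)
})

test_that("y-down input flips into analysis space", {
  cfg <- random_config(5)
  f <- withr::local_tempfile(fileext = ".tps")
  flipped <- cfg
  flipped$points[, 2] <- 709 - flipped$points[, 2]
  write_tps(landmark_dataset(list(flipped)), f)
  back <- read_tps(f, y_down = TRUE, image_height = 709)
  expect_equal(back$coords[, , 1], cfg$points, tolerance = 1e-8)
  expect_error(read_tps(f, y_down = TRUE), "image_height")
})

test_that("curve construction pins anchors and fills runs by equal arc length", {
  expect_equal(unname(anchor_indices()), c(1L, 5L, 8L, 15L, 27L, 28L, 29L, 30L))
  expect_equal(8 + sum(insert_counts()), 30)

  # collinear, evenly spaced anchors: all 30 points collinear and equally
  # spaced within each run
  A <- cbind(seq(0, 70, by = 10), seq(0, 35, by = 5))
  cfg <- build_curve_landmarks(anchor_set(A))
  pts <- cfg$points
  expect_equal(nrow(pts), 30)
  resid <- pts[, 2] - 0.5 * pts[, 1]
  expect_lt(max(abs(resid)), 1e-8)
  idx <- anchor_indices()
  for (run in 1:4) {
    seg <- pts[idx[run]:idx[run + 1], 1]
    expect_equal(diff(seg), rep(diff(seg)[1], length(seg) - 1),
                 tolerance = 1e-6)
  }
  # anchors pinned bit-exactly
  expect_identical(unname(pts[unname(idx), ]),
                   unname(unclass(anchor_set(A))))

  # template anchors land at their canonical indices too
  tpl <- template_anchors()
  cfg2 <- build_curve_landmarks(tpl)
  expect_identical(unname(cfg2$points[unname(idx), ]),
                   unname(unclass(tpl)))
})

test_that("curve construction is equivariant under rigid motion", {
  tpl <- unclass(template_anchors())
  base <- build_curve_landmarks(anchor_set(tpl))$points
  for (theta in c(0.3, 1.2, 2.8)) {
    moved <- similarity_transform(tpl, theta, 1, c(17, -40))
    got <- build_curve_landmarks(anchor_set(moved))$points
    expect_equal(unname(got),
                 unname(similarity_transform(base, theta, 1, c(17, -40))),
                 tolerance = 1e-8)
  }
})

test_that("degenerate anchor sets are rejected", {
  A <- unclass(template_anchors())
  A[2, ] <- A[1, ]
  expect_error(anchor_set(A), "coincident")
})

test_that("interior angles match closed forms and the HNA windows", {
  expect_equal(compute_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(compute_angle(c(1, 0), c(0, 0), c(-1, 0)), 180)
  expect_lt(compute_angle(c(5, 5), c(0, 0), c(10, 10)), 1e-4)
  expect_error(compute_angle(c(0, 0), c(0, 0), c(1, 1)), "zero-length")

  # the template generator constructs its HNA exactly; verify through
  # compute_angle for open and closed postures
  for (hna in c(110, 112.5, 115, 85, 90)) {
    A <- unclass(template_anchors(hna))
    got <- compute_angle(A["T10", ], A["atlantooccipital", ],
                         A["temporomandibular", ])
    expect_equal(got, hna, tolerance = 1e-9)
  }
  set.seed(8)
  open_hnas <- runif(20, hna_window("open")[1], hna_window("open")[2])
  for (hna in open_hnas) {
    A <- unclass(template_anchors(hna))
    got <- compute_angle(A["T10", ], A["atlantooccipital", ],
                         A["temporomandibular", ])
    expect_gte(got, 110); expect_lte(got, 115)
  }
})
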