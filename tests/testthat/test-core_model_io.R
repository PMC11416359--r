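# core_model_io: containers, readers/writers, margin classification

make_random_volume <- function(seed = 5) {
  withr::with_seed(seed, {
    v <- array(0L, c(12, 9, 7))
    v[3:9, 3:7, 2:6] <- 1L
    v[5:7, 4:5, 3:5] <- 2L
    v[4, 4, 2:6] <- 3L
    label_volume(v, spacing = c(0.17, 0.23, 0.5), origin = c(-1, 0.5, 2))
  })
}

test_that("NRRD round-trips across encodings and NIfTI across compression", {
  vol <- make_random_volume()
  for (enc in c("ascii", "raw", "gzip")) {
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_label_volume(vol, f, encoding = enc)
    back <- read_label_volume(f)
    expect_identical(back$voxels, vol$voxels, label = enc)
    expect_equal(back$spacing, vol$spacing)
    expect_equal(back$origin, vol$origin)
  }
  for (ext in c(".nii", ".nii.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_label_volume(vol, f)
    back <- read_label_volume(f)
    expect_identical(back$voxels, vol$voxels, label = ext)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  }
})

test_that("reading an all-zero volume yields zero foreground", {
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_label_volume(label_volume(array(0L, c(10, 10, 10)),
                                  spacing = c(0.1, 0.1, 0.5)), f)
  vol <- read_label_volume(f)
  expect_identical(sum(vol$voxels > 0L), 0L)
  expect_equal(vol$spacing, c(0.1, 0.1, 0.5))
})

test_that("volume validation names the defect", {
  v <- array(0L, c(5, 5, 5)); v[2, 2, 2] <- 7L
  expect_error(label_volume(v), "7")
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_label_volume(label_volume(v, validate = FALSE), f)
  expect_error(read_label_volume(f), "7")
  expect_error(label_volume(array(0L, c(3, 3, 3)), spacing = c(1, -1, 1)),
               "spacing")
  # tumor floating in background, disconnected from the specimen
  v2 <- array(0L, c(8, 8, 8)); v2[2:3, 2:3, 2:3] <- 1L; v2[6:7, 6:7, 6:7] <- 2L
  expect_error(label_volume(v2), "disconnected")
  expect_error(read_label_volume(withr::local_tempfile(fileext = ".xyz")),
               "not found|format")
})

test_that("slide stacks round-trip bit-exact through PNG + sidecar", {
  stk <- PH0$stack
  d <- withr::local_tempdir()
  write_slide_stack(stk, d)
  back <- read_slide_stack(d)
  expect_identical(back$slides, stk$slides)
  expect_equal(back$spacing, stk$spacing)
  expect_equal(back$slice_thickness, stk$slice_thickness)
  expect_equal(back$origin, stk$origin, tolerance = 1e-9)
  expect_identical(back$orientation$x_positive, stk$orientation$x_positive)
  for (i in seq_along(stk$slides)) {
    if (is.null(stk$mucosal_edges[[i]])) expect_null(back$mucosal_edges[[i]])
    else expect_equal(unname(back$mucosal_edges[[i]]),
                      unname(stk$mucosal_edges[[i]]), tolerance = 1e-9)
  }
})

test_that("slide stack reader reports structural defects", {
  d <- withr::local_tempdir()
  expect_error(read_slide_stack(d), "no slides")

  stk <- PH0$stack
  write_slide_stack(stk, d)
  meta <- jsonlite::read_json(file.path(d, "slides.json"))
  expect_equal(meta$slice_thickness, 4)
  expect_length(meta$slides, length(stk$slides))

  meta2 <- meta
  meta2$slides[[2]]$index <- 7L + length(stk$slides)
  jsonlite::write_json(meta2, file.path(d, "slides.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  expect_error(read_slide_stack(d), "gaps|duplicates")

  meta3 <- meta
  meta3$slides[[3]]$mucosal_edges <- list(list(1e5, 1e5), list(-1e5, 0))
  jsonlite::write_json(meta3, file.path(d, "slides.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  expect_error(read_slide_stack(d), "outside")

  meta4 <- meta
  meta4$pixel_spacing <- NULL
  jsonlite::write_json(meta4, file.path(d, "slides.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  expect_error(read_slide_stack(d), "spacing")
})

test_that("mucosal edges must sit on the tissue boundary", {
  stk <- PH0$stack
  i <- which(vapply(stk$slides, function(m) any(m == 2L), TRUE))[1]
  bad <- stk
  bad$mucosal_edges[[i]] <- matrix(c(0, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(validate_slide_stack(bad), "boundary")
  expect_warning(
    validate_slide_stack(slide_stack(stk$slides, spacing = stk$spacing,
                                     orientation = stk$orientation,
                                     origin = stk$origin, validate = FALSE)),
    "without mucosal edges")
})

test_that("margin classification follows the 5 mm close-margin convention", {
  expect_identical(classify_margin(c(4.9, 5.0, 0.0)),
                   c("close", "clear", "involved"))
  expect_error(classify_margin(-0.1), "0")
  # monotone: walking the margin down never improves the category
  ms <- margin_status()
  lev <- c(involved = 0, close = 1, clear = 2)
  cats <- lev[classify_margin(seq(10, 0, by = -0.25), ms)]
  expect_true(all(diff(cats) <= 0))
  # configurable thresholds
  ms2 <- margin_status(threshold_close = 3, threshold_involved = 1)
  expect_identical(classify_margin(c(0.5, 2, 3), ms2),
                   c("involved", "close", "clear"))
  expect_error(margin_status(threshold_close = 1, threshold_involved = 2), "<")
})

test_that("measurement records round-trip through CSV", {
  rec <- toy_record("P1", "US-manual", 1:3, c(5, 6, 7),
                    anterior = 4, posterior = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(rec, f)
  back <- read_measurements(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  writeLines("a,b\n1,2", f)
  expect_error(read_measurements(f), "lacks")
  expect_error(measurement_record("P1", "histology",
                                  slice = data.frame(slide = 1, TT = -1,
                                                     cranial = 1, deep = 1,
                                                     caudal = 1)),
               "negative")
})
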