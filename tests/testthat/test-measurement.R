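# measurement: 45-degree partition and the six distance operations

# square tissue mask with mucosa along the top (max y) edge
square_case <- function(n = 41, spacing = 1) {
  mask <- matrix(0L, n + 4, n + 4)
  mask[3:(n + 2), 3:(n + 2)] <- 1L
  org <- c(0, 0)
  top <- (n + 2 - 1) * spacing       # world y of the top tissue row
  left <- (3 - 1) * spacing
  right <- (n + 2 - 1) * spacing
  edges <- rbind(c(left, top), c(right, top))
  list(mask = mask, edges = edges, spacing = c(spacing, spacing), org = org)
}

test_that("square tissue partitions into deep bottom and lateral sides", {
  sq <- square_case()
  part <- partition_resection_surface(sq$mask, sq$edges,
                                      list(x_positive = "cranial"),
                                      sq$spacing, sq$org)
  reg <- split(as.data.frame(part$world), part$region[])
  # mucosal arc = the top edge (between the two corners)
  expect_true(all(reg$mucosal[, 2] == max(part$world[, 2])))
  # deep region contains the whole bottom edge (corners included)
  bottom <- part$world[, 2] == min(part$world[, 2])
  expect_true(all(part$region[bottom] == "deep"))
  # lateral regions sit on the two vertical edges, split at 45 degrees
  expect_true(all(reg$cranial[, 1] == max(part$world[, 1])))
  expect_true(all(reg$caudal[, 1] == min(part$world[, 1])))
  expect_equal(nrow(reg$cranial), nrow(reg$caudal))
})

test_that("mirroring the image with a flipped tag swaps cranial and caudal", {
  sq <- square_case()
  part <- partition_resection_surface(sq$mask, sq$edges,
                                      list(x_positive = "cranial"),
                                      sq$spacing, sq$org)
  mmask <- sq$mask[nrow(sq$mask):1, ]
  xmax <- (nrow(sq$mask) - 1) * sq$spacing[1]
  medges <- cbind(xmax - sq$edges[, 1], sq$edges[, 2])
  mpart <- partition_resection_surface(mmask, medges,
                                       list(x_positive = "caudal"),
                                       sq$spacing, sq$org)
  key <- function(p, r) {
    w <- p$world[p$region == r, , drop = FALSE]
    sort(paste(round(w[, 1], 6), round(w[, 2], 6)))
  }
  mirror_key <- function(p, r) {
    w <- p$world[p$region == r, , drop = FALSE]
    sort(paste(round(xmax - w[, 1], 6), round(w[, 2], 6)))
  }
  expect_identical(key(part, "cranial"), mirror_key(mpart, "cranial"))
  expect_identical(key(part, "caudal"), mirror_key(mpart, "caudal"))
  expect_identical(key(part, "deep"), mirror_key(mpart, "deep"))
})

test_that("partition regions are disjoint and cover the boundary on phantom slices", {
  for (ph in list(PH0, PH2)) {
    for (ts in tumor_slides(ph)) {
      part <- partition_resection_surface(ts$mask, ts$edges, ts$orientation,
                                          ts$spacing, ts$origin)
      expect_identical(nrow(part$boundary),
                       nrow(sonomargin:::boundary_pixels(ts$mask > 0L)))
      expect_false(any(is.na(part$region)))
      expect_true(all(table(part$region)[c("cranial", "deep", "caudal")] > 0))
    }
  }
})

test_that("degenerate edge inputs are rejected", {
  sq <- square_case()
  expect_error(partition_resection_surface(sq$mask,
                                           rbind(c(2, 42), c(2, 42)),
                                           list(x_positive = "cranial"),
                                           sq$spacing, sq$org),
               "coincide")
  expect_error(partition_resection_surface(sq$mask,
                                           rbind(c(20, 20), c(22, 20)),
                                           list(x_positive = "cranial"),
                                           sq$spacing, sq$org),
               "boundary")
  part <- partition_resection_surface(sq$mask, sq$edges,
                                      list(x_positive = "cranial"),
                                      sq$spacing, sq$org)
  expect_error(region_margin(sq$mask + 0L, part, "ventral"), "unknown|tumor")
})

test_that("tumor adjacent to the deep surface yields a one-pixel margin", {
  sq <- square_case(spacing = 0.5)
  mask <- sq$mask
  mask[10:20, 4] <- 2L   # one row above the bottom tissue row (row 3)
  part <- partition_resection_surface(mask, sq$edges,
                                      list(x_positive = "cranial"),
                                      sq$spacing, sq$org)
  expect_equal(region_margin(mask, part, "deep"), 0.5)
})

test_that("radially symmetric disk gives equal margins in all regions", {
  n <- 81
  cx <- (n + 1) / 2
  ij <- expand.grid(i = 1:n, j = 1:n)
  r2 <- (ij$i - cx)^2 + (ij$j - cx)^2
  mask <- matrix(0L, n, n)
  mask[r2 <= 38^2] <- 1L
  mask[r2 <= 12^2] <- 2L
  th <- c(45, 135) * pi / 180
  edges <- cbind(cx - 1 + 38 * cos(th), cx - 1 + 38 * sin(th))
  part <- partition_resection_surface(mask, edges,
                                      list(x_positive = "cranial"),
                                      c(1, 1), c(0, 0))
  m <- c(region_margin(mask, part, "cranial"),
         region_margin(mask, part, "deep"),
         region_margin(mask, part, "caudal"))
  expect_lt(max(m) - min(m), sqrt(2))
})

test_that("per-slice measurements equal their brute-force oracles exactly", {
  n_checked <- 0
  for (ph in list(PH0, PH2)) {
    for (ts in tumor_slides(ph)) {
      part <- partition_resection_surface(ts$mask, ts$edges, ts$orientation,
                                          ts$spacing, ts$origin)
      for (rg in c("cranial", "deep", "caudal")) {
        got <- region_margin(ts$mask, part, rg)
        want <- brute_region_margin(ts$mask, part, rg, ts$spacing)
        expect_equal(got, want, tolerance = 1e-12)
      }
      expect_equal(tumor_thickness(ts$mask, part),
                   brute_tumor_thickness(ts$mask, part, ts$spacing, ts$origin),
                   tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 5)
})

test_that("tumor thickness handles rectangles and degenerate tumors", {
  sq <- square_case(spacing = 0.5)
  mask <- sq$mask
  mask[10:30, 12:21] <- 2L    # 10 rows of 0.5 mm -> 4.5 mm center-to-center? no:
  part <- partition_resection_surface(mask, sq$edges,
                                      list(x_positive = "cranial"),
                                      sq$spacing, sq$org)
  # chord is horizontal, normal vertical: extent = (21 - 12) * 0.5 = 4.5;
  # use 11 rows for exactly 5 mm
  mask2 <- sq$mask
  mask2[10:30, 12:22] <- 2L
  expect_equal(tumor_thickness(mask2, part), 5)
  mask3 <- sq$mask
  mask3[15, 15] <- 2L
  expect_warning(tt <- tumor_thickness(mask3, part), "single-pixel")
  expect_equal(tt, 0)
})

test_that("histology end margins apply the tumor-free-slide counting rule", {
  blank <- matrix(0L, 20, 20); blank[5:15, 5:15] <- 1L
  tum <- blank; tum[8:12, 8:12] <- 2L
  mk <- function(k, m = 6) {
    slides <- c(replicate(k, blank, simplify = FALSE),
                list(tum, tum),
                replicate(m - k - 2, blank, simplify = FALSE))
    slide_stack(slides, spacing = c(1, 1), validate = FALSE)
  }
  expect_equal(unname(end_margins_histology(mk(0))["anterior"]), 0)
  expect_equal(unname(end_margins_histology(mk(1))["anterior"]), 4)
  expect_equal(unname(end_margins_histology(mk(3, m = 7))["anterior"]), 12)
  expect_equal(unname(end_margins_histology(mk(1))["posterior"]),
               (6 - 1 - 2) * 4)
  expect_error(end_margins_histology(mk(0, m = 2)), NA)
  empty <- slide_stack(list(blank, blank), spacing = c(1, 1), validate = FALSE)
  expect_error(end_margins_histology(empty), "no tumor")
})

test_that("US end margins: cap contact gives zero, and the oracle agrees", {
  v <- array(0L, c(10, 10, 20))
  v[3:8, 3:8, 2:18] <- 1L
  v[4:6, 4:6, 2:6] <- 2L     # tumor touching the anterior extent
  vol <- label_volume(v, spacing = c(0.5, 0.5, 0.5))
  em <- end_margins_us(vol)
  expect_equal(unname(em["anterior"]), 0)
  expect_equal(unname(em["posterior"]), (18 - 6) * 0.5)
  for (ph in list(PH0, PH2)) {
    expect_equal(end_margins_us(ph$volume), brute_end_margins_us(ph$volume))
  }
})

test_that("measurements are invariant under in-plane rotation", {
  ts <- tumor_slides(PH0)[[2]]
  part <- partition_resection_surface(ts$mask, ts$edges, ts$orientation,
                                      ts$spacing, ts$origin)
  vals <- c(TT = tumor_thickness(ts$mask, part),
            cranial = region_margin(ts$mask, part, "cranial"),
            deep = region_margin(ts$mask, part, "deep"),
            caudal = region_margin(ts$mask, part, "caudal"))
  # rotate 90 degrees: (i, j) -> (j, ni + 1 - i); world accordingly
  m90 <- t(ts$mask)[, nrow(ts$mask):1]
  ni <- nrow(ts$mask)
  rot <- function(p) cbind(p[, 2] - ts$origin[2],
                           (ts$origin[1] + (ni - 1) * ts$spacing[1]) - p[, 1])
  e90 <- rot(ts$edges)
  # a 90-degree rotation swaps the anatomical sides seen by the x axis
  part90 <- partition_resection_surface(m90, e90,
                                        list(x_positive = "cranial"),
                                        rev(ts$spacing), c(0, 0))
  vals90 <- c(TT = tumor_thickness(m90, part90),
              cranial = region_margin(m90, part90, "cranial"),
              deep = region_margin(m90, part90, "deep"),
              caudal = region_margin(m90, part90, "caudal"))
  expect_equal(vals90[["TT"]], vals[["TT"]], tolerance = 1e-9)
  expect_equal(vals90[["deep"]], vals[["deep"]], tolerance = 1e-9)
  expect_equal(sort(c(vals90[["cranial"]], vals90[["caudal"]])),
               sort(c(vals[["cranial"]], vals[["caudal"]])), tolerance = 1e-9)
})

test_that("dilating the tumor never increases any margin", {
  dilate <- function(mask) {
    fg <- mask == 2L
    nb <- fg
    nb[-1, ] <- nb[-1, ] | fg[-nrow(fg), ]
    nb[-nrow(fg), ] <- nb[-nrow(fg), ] | fg[-1, ]
    nb[, -1] <- nb[, -1] | fg[, -ncol(fg)]
    nb[, -ncol(fg)] <- nb[, -ncol(fg)] | fg[, -1]
    out <- mask
    out[nb & mask > 0L] <- 2L
    out
  }
  for (ts in tumor_slides(PH0)[1:3]) {
    part <- partition_resection_surface(ts$mask, ts$edges, ts$orientation,
                                        ts$spacing, ts$origin)
    big <- dilate(ts$mask)
    for (rg in c("cranial", "deep", "caudal")) {
      m0 <- region_margin(ts$mask, part, rg)
      m1 <- region_margin(big, part, rg)
      if (!is.na(m0) && !is.na(m1)) expect_lte(m1, m0)
    }
  }
})

test_that("region margins bound the unconstrained closest surface distance", {
  for (ts in tumor_slides(PH2)) {
    part <- partition_resection_surface(ts$mask, ts$edges, ts$orientation,
                                        ts$spacing, ts$origin)
    d2 <- sonomargin:::.edt2d_sq(ts$mask == 2L, ts$spacing[1], ts$spacing[2])
    non_muc <- part$boundary[part$region != "mucosal", , drop = FALSE]
    free_min <- min(sqrt(d2[non_muc]))
    margins <- vapply(c("cranial", "deep", "caudal"), function(rg)
      region_margin(ts$mask, part, rg), 0.0)
    expect_true(all(margins >= free_min - 1e-12, na.rm = TRUE))
    expect_equal(min(margins, na.rm = TRUE), free_min)
  }
})

test_that("measure_specimen produces blinded records plus discordance table", {
  corr <- match_slides(PH2$volume, PH2$stack)
  out <- measure_specimen(PH2$volume, PH2$stack, corr, PH2$landmarks)
  expect_s3_class(out$us, "measurement_record")
  expect_s3_class(out$histo, "measurement_record")
  expect_true(all(out$us$value_mm >= 0))
  expect_identical(unique(out$us$modality), "US-manual")
  expect_identical(unique(out$histo$modality), "histology")
  expect_true(is.data.frame(out$discordant))
  expect_true(all(c("anterior", "posterior") %in% out$us$measure))
})
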