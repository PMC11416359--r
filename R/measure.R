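# Geometric core: partition of the resection surface into cranial / deep /
# caudal at +-45 degrees from the mucosal chord, and the spacing-aware
# distance measurements. All distances are physical mm; per-slice margins
# are 2D in-plane (what a pathologist measures on a WSI), end margins on
# the US side are 3D.

# boundary pixels of a logical mask: foreground with a 4-neighbor outside
# the foreground (image edge counts as outside); returns index matrix [ix, iy]
boundary_pixels <- function(fg) {
  nx <- nrow(fg); ny <- ncol(fg)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- fg
  core <- pad[2:(nx + 1), 2:(ny + 1)]
  full <- pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
    pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
  which(core & !full, arr.ind = TRUE)
}

pixel_world <- function(idx, spacing, origin) {
  cbind(origin[1] + (idx[, 1] - 1) * spacing[1],
        origin[2] + (idx[, 2] - 1) * spacing[2])
}

#' Partition the resection surface of a slice into three regions
#'
#' Draws the chord between the two mucosal-edge points, takes its
#' midpoint, and casts two rays at +-45 degrees (measured in physical mm,
#' so anisotropic pixels cannot distort the angle) into the tissue.
#' Boundary pixels on the mucosal side of the chord form the mucosal arc
#' (excluded from the resection surface); every remaining boundary pixel
#' is assigned cranial, deep or caudal by its angular position about the
#' midpoint, with the cranial/caudal sides resolved from the stack's
#' orientation tag.
#'
#' @param mask 2D integer label matrix (0 background, 1 tissue, 2 tumor,
#'   3 fiducial hole; labels > 0 all count as tissue foreground).
#' @param edges 2x2 matrix of the two mucosal-edge points (rows = points,
#'   columns = x, y in world mm).
#' @param orientation orientation tag, a list with `x_positive` in
#'   \{"cranial", "caudal"\}.
#' @param spacing pixel spacing (px, py) mm.
#' @param origin world position of pixel (1,1) center, mm.
#' @return object of class `region_partition`: boundary pixel indices and
#'   world coordinates, per-pixel region factor, chord frame.
#' @export
partition_resection_surface <- function(mask, edges, orientation,
                                        spacing = c(1, 1), origin = c(0, 0)) {
  fg <- mask > 0L
  if (!any(fg)) stopf("slice has no tissue")
  e1 <- as.numeric(edges[1, ]); e2 <- as.numeric(edges[2, ])
  if (sqrt(sum((e1 - e2)^2)) < 1e-9) stopf("mucosal edge points coincide")
  b <- boundary_pixels(fg)
  bw <- pixel_world(b, spacing, origin)
  tol <- 2 * max(spacing) + 1e-9
  for (e in list(e1, e2)) {
    if (sqrt(min((bw[, 1] - e[1])^2 + (bw[, 2] - e[2])^2)) > tol)
      stopf("mucosal edge point (%.2f, %.2f) is not near the tissue boundary",
            e[1], e[2])
  }
  fgw <- pixel_world(which(fg, arr.ind = TRUE), spacing, origin)
  frame <- chord_frame(e1, e2, toward = colMeans(fgw))
  reg <- region_of_points(bw, frame, orientation$x_positive)
  structure(list(boundary = b, world = bw,
                 region = factor(reg, levels = c("mucosal", "cranial",
                                                 "deep", "caudal")),
                 frame = frame, edges = rbind(e1, e2),
                 spacing = spacing, origin = origin),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>", nrow(x$boundary), "boundary pixels:",
      paste(sprintf("%s=%d", levels(x$region), table(x$region)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-region resection margin on a slice
#'
#' Minimum physical Euclidean distance between any tumor pixel and any
#' resection-surface pixel of the named region, computed with an exact
#' anisotropic Euclidean distance transform from the tumor. Absent (NA)
#' if the region has no surface pixels.
#'
#' @param mask 2D label matrix (tumor = 2).
#' @param partition a [partition_resection_surface()] result.
#' @param region one of `"cranial"`, `"deep"`, `"caudal"`.
#' @param spacing pixel spacing (px, py) mm.
#' @return margin in mm, or NA if the region is empty.
#' @export
region_margin <- function(mask, partition, region, spacing = partition$spacing) {
  if (!region %in% c("cranial", "deep", "caudal"))
    stopf("unknown region '%s'", region)
  if (!any(mask == 2L)) stopf("slice has no tumor pixels")
  sel <- partition$region == region
  if (!any(sel)) return(NA_real_)
  d2 <- .edt2d_sq(mask == 2L, spacing[1], spacing[2])
  min(sqrt(d2[partition$boundary[sel, , drop = FALSE]]))
}

#' Tumor thickness on a slice
#'
#' Maximum thickness of the tumor, defined as the extent of tumor pixel
#' centers projected onto the chord-normal axis (max minus min
#' projection), in mm. This direction-based definition handles exophytic
#' tumors and is rotation-consistent.
#'
#' @inheritParams region_margin
#' @return thickness in mm; a single tumor pixel yields 0 with a
#'   thin-tumor warning.
#' @export
tumor_thickness <- function(mask, partition, spacing = partition$spacing) {
  idx <- which(mask == 2L, arr.ind = TRUE)
  if (!nrow(idx)) return(NA_real_)
  tw <- pixel_world(idx, spacing, partition$origin)
  pr <- (tw[, 1] - partition$frame$mid[1]) * partition$frame$w[1] +
    (tw[, 2] - partition$frame$mid[2]) * partition$frame$w[2]
  tt <- max(pr) - min(pr)
  if (nrow(idx) == 1L)
    warning("single-pixel tumor: thickness degenerates to 0", call. = FALSE)
  tt
}

#' Anterior/posterior margins from a histology stack
#'
#' The pathologist's counting rule: the number of consecutive tumor-free
#' slides before the first (after the last) tumor-bearing slide,
#' multiplied by the slice thickness.
#'
#' @param stack a [slide_stack()].
#' @return named numeric `c(anterior, posterior)` in mm.
#' @export
end_margins_histology <- function(stack) {
  has_tumor <- vapply(stack$slides, function(m) any(m == 2L), TRUE)
  if (!any(has_tumor))
    stopf("no tumor in any slide of specimen '%s'", stack$specimen)
  c(anterior = (which(has_tumor)[1] - 1) * stack$slice_thickness,
    posterior = (length(has_tumor) - max(which(has_tumor))) * stack$slice_thickness)
}

#' Anterior/posterior margins from the US volume
#'
#' Distance from the tumor annotation to the anterior (min-z) and
#' posterior (max-z) end of the specimen annotation, measured along the
#' sweep/sectioning axis: the z-distance from the extreme tumor voxel
#' center to the specimen's extreme z extent. This is the quantity the
#' histology counting rule discretizes (tumor-free slides x 4 mm), so the
#' two modalities measure the same construct; a full 3D distance to the
#' end-cap surface would instead take a diagonal shortcut across the
#' tapering nose of the specimen that slice counting cannot see.
#'
#' @param volume a [label_volume()].
#' @return named numeric `c(anterior, posterior)` in mm.
#' @export
end_margins_us <- function(volume) {
  v <- volume$voxels
  if (!any(v == 2L)) stopf("no tumor voxels in volume")
  fg <- v > 0L
  zw <- volume_axis(volume, 3)
  kz <- which(apply(fg, 3, any))
  tz <- which(apply(v == 2L, 3, any))
  c(anterior = zw[min(tz)] - zw[min(kz)], posterior = zw[max(kz)] - zw[max(tz)])
}

# measure one 2D slice: partition + TT + three region margins
measure_slice <- function(mask, edges, orientation, spacing, origin) {
  part <- partition_resection_surface(mask, edges, orientation, spacing, origin)
  list(TT = tumor_thickness(mask, part),
       cranial = region_margin(mask, part, "cranial"),
       deep = region_margin(mask, part, "deep"),
       caudal = region_margin(mask, part, "caudal"))
}

#' Measure a histology slide stack
#'
#' Runs the per-slice measurements on every tumor-bearing slide (using its
#' mucosal-edge landmarks) and the tumor-free-slide counting rule for the
#' end margins. Tumor-bearing slides without landmarks are skipped with a
#' warning (they cannot be partitioned).
#'
#' @param stack a [slide_stack()].
#' @return a [measurement_record()] with modality `"histology"`.
#' @export
measure_histology <- function(stack) {
  has_tumor <- vapply(stack$slides, function(m) any(m == 2L), TRUE)
  if (!any(has_tumor))
    stopf("no tumor in any slide of specimen '%s'", stack$specimen)
  rows <- list()
  for (i in which(has_tumor)) {
    e <- stack$mucosal_edges[[i]]
    if (is.null(e)) {
      warning(sprintf("slide %d: tumor present but no mucosal edges; skipped", i),
              call. = FALSE)
      next
    }
    m <- measure_slice(stack$slides[[i]], e, stack$orientation,
                       stack$spacing, stack$origin)
    rows[[length(rows) + 1]] <- data.frame(slide = i, TT = m$TT,
                                           cranial = m$cranial, deep = m$deep,
                                           caudal = m$caudal)
  }
  ends <- end_margins_histology(stack)
  measurement_record(stack$specimen, "histology",
                     slice = if (length(rows)) do.call(rbind, rows) else NULL,
                     anterior = ends["anterior"], posterior = ends["posterior"])
}

#' Measure the US volume at the slices matched to the histology slides
#'
#' For every histology slide, extracts the matched US elevation slice
#' (via the correspondence), partitions it with its mucosal-edge
#' landmarks, and measures TT and the three region margins, so that US
#' measurements are made in the same location as the slides. End margins
#' use the 3D rule of [end_margins_us()]. Slides whose matched US slice
#' shows no tumor yield no entry (the pairing step reports them as
#' discordant detections).
#'
#' @param volume a [label_volume()].
#' @param correspondence a [match_slides()] result.
#' @param landmarks data.frame (`index`, `x1`, `y1`, `x2`, `y2`): the two
#'   mucosal-edge points per US elevation index, world mm.
#' @param orientation orientation tag (see [slide_stack()]).
#' @param modality `"US-manual"` or `"US-auto"`.
#' @return a [measurement_record()].
#' @export
measure_us <- function(volume, correspondence, landmarks,
                       orientation = list(x_positive = "cranial"),
                       modality = "US-manual") {
  rows <- list()
  for (k in seq_len(nrow(correspondence$slides))) {
    i <- correspondence$slides$slide[k]
    iz <- correspondence$slides$index[k]
    mask <- volume$voxels[, , iz]
    if (!any(mask == 2L)) next
    lm <- landmarks[landmarks$index == iz, , drop = FALSE]
    if (!nrow(lm)) {
      warning(sprintf("US slice %d (slide %d): no mucosal-edge landmarks; skipped",
                      iz, i), call. = FALSE)
      next
    }
    e <- rbind(c(lm$x1[1], lm$y1[1]), c(lm$x2[1], lm$y2[1]))
    m <- measure_slice(mask, e, orientation, volume$spacing[1:2],
                       volume$origin[1:2])
    rows[[length(rows) + 1]] <- data.frame(slide = i, TT = m$TT,
                                           cranial = m$cranial, deep = m$deep,
                                           caudal = m$caudal)
  }
  ends <- end_margins_us(volume)
  measurement_record(correspondence$specimen, modality,
                     slice = if (length(rows)) do.call(rbind, rows) else NULL,
                     anterior = ends["anterior"], posterior = ends["posterior"])
}

#' Measure one specimen in both modalities
#'
#' Convenience wrapper running [measure_us()] and [measure_histology()]
#' (each blinded to the other) and recording discordant detections: slides
#' where one modality shows tumor and the other does not — superficial or
#' filamentous tumors may not be detected by US — are listed, not silently
#' dropped.
#'
#' @param volume a [label_volume()].
#' @param stack the corresponding [slide_stack()].
#' @param correspondence a [match_slides()] result.
#' @param landmarks US mucosal-edge landmark table (see [measure_us()]).
#' @param modality US modality label.
#' @return list with `us` and `histo` measurement records and a
#'   `discordant` data.frame (`slide`, `us_tumor`, `histo_tumor`).
#' @export
measure_specimen <- function(volume, stack, correspondence, landmarks,
                             modality = "US-manual") {
  us <- measure_us(volume, correspondence, landmarks, stack$orientation,
                   modality)
  histo <- measure_histology(stack)
  ht <- vapply(stack$slides, function(m) any(m == 2L), TRUE)
  ut <- vapply(seq_len(nrow(correspondence$slides)), function(k)
    any(volume$voxels[, , correspondence$slides$index[k]] == 2L), TRUE)
  disc <- data.frame(slide = correspondence$slides$slide,
                     us_tumor = ut, histo_tumor = ht)
  disc <- disc[xor(disc$us_tumor, disc$histo_tumor), , drop = FALSE]
  list(us = us, histo = histo, discordant = disc)
}
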