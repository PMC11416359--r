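#' Ordered histology slide stack
#'
#' Container for the histopathology side: one 2D label mask per 4 mm
#' slice, ordered anterior to posterior along the sectioning axis.
#' Labels: 0 = background, 1 = tissue, 2 = tumor, 3 = fiducial hole (the
#' artificial channel left after removing the IV cannula). Each slide may
#' carry the two mucosal-edge landmarks (mm, world 2D coordinates) where
#' the mucosal surface meets the resection surface.
#'
#' Masks are integer matrices indexed `[ix, iy]` with world coordinates
#' `origin + (index - 1) * spacing` at pixel centers.
#'
#' @param slides list of integer matrices (labels 0-3), anterior first.
#' @param spacing numeric length-2 pixel spacing (px, py) mm.
#' @param slice_thickness section thickness in mm (default 4, the
#'   standard histopathological cut).
#' @param orientation list tag mapping image axes to anatomy; at minimum
#'   `x_positive`, one of `"cranial"` or `"caudal"`: the anatomical
#'   direction of increasing x. Carried as explicit metadata because masks
#'   cannot encode the sutures/ink used for orientation.
#' @param mucosal_edges list (one per slide) of 2x2 matrices (rows =
#'   points, columns = x, y in mm), or `NULL` where absent.
#' @param origin numeric length-2 world position of pixel (1,1) center, mm.
#' @param specimen specimen identifier.
#' @param validate run invariant checks.
#' @return object of class `slide_stack`.
#' @export
slide_stack <- function(slides, spacing = c(0.1, 0.1), slice_thickness = 4,
                        orientation = list(x_positive = "cranial"),
                        mucosal_edges = NULL, origin = c(0, 0),
                        specimen = "specimen", validate = TRUE) {
  if (!length(slides)) stopf("no slides")
  slides <- lapply(slides, function(m) { storage.mode(m) <- "integer"; m })
  if (is.null(mucosal_edges)) mucosal_edges <- vector("list", length(slides))
  stk <- structure(list(slides = slides, spacing = as.numeric(spacing),
                        slice_thickness = as.numeric(slice_thickness),
                        orientation = orientation,
                        mucosal_edges = mucosal_edges,
                        origin = as.numeric(origin), specimen = specimen),
                   class = "slide_stack")
  if (validate) validate_slide_stack(stk)
  stk
}

#' Validate slide-stack invariants
#'
#' Checks spacing and thickness positivity, the label set, orientation tag,
#' and that every supplied mucosal-edge point lies on or within 2 px of the
#' tissue boundary of its slide. Tumor-bearing slides lacking mucosal edges
#' are reported as a warning (they cannot be measured).
#'
#' @param stk a `slide_stack`.
#' @return the stack, invisibly.
#' @export
validate_slide_stack <- function(stk) {
  if (stk$slice_thickness <= 0) stopf("slice_thickness must be > 0")
  if (any(stk$spacing <= 0)) stopf("pixel spacing must be > 0")
  if (!stk$orientation$x_positive %in% c("cranial", "caudal"))
    stopf("orientation$x_positive must be 'cranial' or 'caudal'")
  if (length(stk$mucosal_edges) != length(stk$slides))
    stopf("mucosal_edges length (%d) != number of slides (%d)",
          length(stk$mucosal_edges), length(stk$slides))
  missing_edges <- integer()
  for (i in seq_along(stk$slides)) {
    m <- stk$slides[[i]]
    bad <- setdiff(unique(as.vector(m)), 0:3)
    if (length(bad))
      stopf("slide %d: invalid labels %s", i, paste(bad, collapse = ", "))
    e <- stk$mucosal_edges[[i]]
    has_tumor <- any(m == 2L)
    if (is.null(e)) {
      if (has_tumor) missing_edges <- c(missing_edges, i)
      next
    }
    if (!is.matrix(e) || !all(dim(e) == c(2L, 2L)))
      stopf("slide %d: mucosal_edges must be a 2x2 matrix", i)
    b <- boundary_pixels(m > 0L)
    if (!nrow(b)) stopf("slide %d: edges supplied but slide has no tissue", i)
    bw <- cbind(stk$origin[1] + (b[, 1] - 1) * stk$spacing[1],
                stk$origin[2] + (b[, 2] - 1) * stk$spacing[2])
    tol <- 2 * max(stk$spacing)
    for (k in 1:2) {
      dmin <- sqrt(min((bw[, 1] - e[k, 1])^2 + (bw[, 2] - e[k, 2])^2))
      if (dmin > tol)
        stopf("slide %d: mucosal edge point %d is %.2f mm from the tissue boundary (> 2 px)",
              i, k, dmin)
    }
  }
  if (length(missing_edges))
    warning(sprintf("tumor-bearing slide(s) without mucosal edges: %s",
                    paste(missing_edges, collapse = ", ")), call. = FALSE)
  invisible(stk)
}

#' @export
print.slide_stack <- function(x, ...) {
  cat(sprintf("<slide_stack> '%s': %d slides, %g mm thick, pixel (%g, %g) mm\n",
              x$specimen, length(x$slides), x$slice_thickness,
              x$spacing[1], x$spacing[2]))
  cat(sprintf("  tumor-bearing slides: %s\n",
              paste(which(vapply(x$slides, function(m) any(m == 2L), TRUE)),
                    collapse = ", ")))
  invisible(x)
}

# nominal z (mm) of slide centers, anterior cap at z = 0 of the stack frame
slide_centers <- function(stk) (seq_along(stk$slides) - 0.5) * stk$slice_thickness

#' Write a slide stack as PNG masks plus a JSON sidecar
#'
#' Each mask is an 8-bit grayscale PNG whose pixel values are the raw
#' labels 0-3 (`mask[ix, iy]` maps to PNG row iy, column ix). The sidecar
#' records order, spacing, thickness, orientation and mucosal edges.
#'
#' @param stk a [slide_stack()].
#' @param dir output directory (created if needed).
#' @param sidecar sidecar file name within `dir`.
#' @return the sidecar path, invisibly.
#' @export
write_slide_stack <- function(stk, dir, sidecar = "slides.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("slide_%03d.png", seq_along(stk$slides))
  for (i in seq_along(stk$slides)) {
    m <- stk$slides[[i]]
    png::writePNG(t(m) / 255, file.path(dir, files[i]))
  }
  meta <- list(
    specimen = stk$specimen,
    pixel_spacing = stk$spacing,
    origin = stk$origin,
    slice_thickness = stk$slice_thickness,
    orientation = stk$orientation,
    slides = lapply(seq_along(stk$slides), function(i) {
      e <- stk$mucosal_edges[[i]]
      list(index = i, file = files[i],
           mucosal_edges = if (is.null(e)) NULL else unname(apply(e, 1, as.list)))
    }))
  jsonlite::write_json(meta, file.path(dir, sidecar), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(file.path(dir, sidecar))
}

#' Read a slide stack from a directory of PNG masks and a JSON sidecar
#'
#' @param dir directory containing the PNG masks.
#' @param sidecar sidecar path; defaults to `slides.json` inside `dir`.
#' @return a [slide_stack()].
#' @export
read_slide_stack <- function(dir, sidecar = file.path(dir, "slides.json")) {
  if (!dir.exists(dir)) stopf("no such directory: '%s'", dir)
  if (!file.exists(sidecar)) {
    if (!length(list.files(dir))) stopf("no slides in '%s'", dir)
    stopf("sidecar not found: '%s'", sidecar)
  }
  meta <- jsonlite::read_json(sidecar)
  if (!length(meta$slides)) stopf("no slides listed in sidecar '%s'", sidecar)
  if (is.null(meta$pixel_spacing)) stopf("sidecar lacks pixel_spacing")
  idx <- vapply(meta$slides, function(s) as.integer(s$index), 1L)
  if (!identical(sort(idx), seq_along(idx)))
    stopf("slide order has gaps or duplicates: indices (%s)",
          paste(idx, collapse = ", "))
  ord <- order(idx)
  spacing <- as.numeric(unlist(meta$pixel_spacing))
  origin <- as.numeric(unlist(meta$origin %||% list(0, 0)))
  slides <- vector("list", length(idx))
  edges <- vector("list", length(idx))
  for (k in seq_along(ord)) {
    s <- meta$slides[[ord[k]]]
    f <- file.path(dir, s$file)
    if (!file.exists(f)) stopf("missing slide file '%s'", f)
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    m <- t(round(img * 255))
    storage.mode(m) <- "integer"
    slides[[k]] <- m
    if (!is.null(s$mucosal_edges)) {
      e <- do.call(rbind, lapply(s$mucosal_edges, function(p) as.numeric(unlist(p))))
      lim <- origin + (dim(m) - 1) * spacing
      if (any(e[, 1] < origin[1] - spacing[1]) || any(e[, 1] > lim[1] + spacing[1]) ||
          any(e[, 2] < origin[2] - spacing[2]) || any(e[, 2] > lim[2] + spacing[2]))
        stopf("slide %d: mucosal edge landmark outside image bounds", k)
      edges[[k]] <- e
    }
  }
  slide_stack(slides, spacing = spacing,
              slice_thickness = as.numeric(meta$slice_thickness %||% 4),
              orientation = lapply(meta$orientation, identity),
              mucosal_edges = edges, origin = origin,
              specimen = meta$specimen %||% "specimen")
}
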