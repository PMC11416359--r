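#' Phantom configuration
#'
#' Parameters of the digital specimen phantom. Defaults emulate the study
#' setting: a convex-ish (superellipsoid) tongue specimen with its longest
#' axis along the anterior-posterior sectioning direction (~30-50 mm long;
#' the study reports no size statistics, so the default 38 mm long axis is
#' an assumption), a mucosal sector on the upper surface, an embedded
#' ellipsoidal tumor, up to three ~1.7 mm (16-gauge) fiducial channels
#' running roughly along z with independent tilts (parallel fiducials
#' would make inter-fiducial distances constant in z and the linearity
#' signal degenerate), uniform linear fixation shrinkage in the cited
#' 11.3-35% range, optional smooth in-plane deformation, and 4 mm
#' sectioning.
#'
#' @param seed integer RNG seed; all phantom randomness derives from it.
#' @param half_axes specimen half-axes (a, b, c) mm; c is along z.
#' @param exponent superellipsoid exponent (2 = ellipsoid; >2 boxier).
#' @param mucosa_sector angular range (degrees, boundary parameter) of the
#'   mucosal surface sector.
#' @param tumor_center tumor center (x, y, z) mm.
#' @param tumor_axes tumor half-axes mm; any zero disables the tumor.
#' @param n_fiducials number of fiducial channels, 0-3.
#' @param fiducial_diameter channel diameter mm (default 1.7, ~16 gauge).
#' @param fiducial_tilt maximum axis tilt from z, degrees.
#' @param shrinkage linear shrinkage fraction s in [0, 0.5); histology
#'   lengths are (1 - s) times US lengths.
#' @param deformation_amp amplitude (mm) of the smooth in-plane warp
#'   applied on top of shrinkage; 0 disables.
#' @param stretch_factor anisotropic elongation emulating a stretched-out,
#'   pinned specimen: histology z-scale is multiplied by this and in-plane
#'   scale by its inverse square root (volume-preserving). 1 = none.
#' @param us_spacing US voxel spacing (dx, dy, dz) mm; dz = 0.5 matches
#'   the motorized sweep reconstruction.
#' @param histo_spacing histology mask pixel spacing (px, py) mm.
#' @param slice_thickness histology section thickness mm (default 4).
#' @param specimen specimen id.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L,
                           half_axes = c(11, 9, 19),
                           exponent = 2.5,
                           mucosa_sector = c(45, 135),
                           tumor_center = c(1.5, 2.5, 0),
                           tumor_axes = c(5.5, 4.5, 8),
                           n_fiducials = 3,
                           fiducial_diameter = 1.7,
                           fiducial_tilt = 10,
                           shrinkage = 0.2,
                           deformation_amp = 0,
                           stretch_factor = 1,
                           us_spacing = c(0.2, 0.2, 0.5),
                           histo_spacing = c(0.1, 0.1),
                           slice_thickness = 4,
                           specimen = "P1") {
  cfg <- list(seed = as.integer(seed), half_axes = as.numeric(half_axes),
              exponent = exponent, mucosa_sector = as.numeric(mucosa_sector),
              tumor_center = as.numeric(tumor_center),
              tumor_axes = as.numeric(tumor_axes),
              n_fiducials = as.integer(n_fiducials),
              fiducial_diameter = fiducial_diameter,
              fiducial_tilt = fiducial_tilt, shrinkage = shrinkage,
              deformation_amp = deformation_amp,
              stretch_factor = stretch_factor,
              us_spacing = as.numeric(us_spacing),
              histo_spacing = as.numeric(histo_spacing),
              slice_thickness = slice_thickness, specimen = specimen)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$half_axes <= 0)) stopf("specimen half-axes must be > 0")
  if (cfg$shrinkage < 0 || cfg$shrinkage >= 1)
    stopf("shrinkage must satisfy 0 <= s < 1, got %g", cfg$shrinkage)
  if (cfg$n_fiducials < 0 || cfg$n_fiducials > 3)
    stopf("n_fiducials must be 0-3, got %d", cfg$n_fiducials)
  if (cfg$stretch_factor <= 0) stopf("stretch_factor must be > 0")
  if (any(cfg$us_spacing <= 0) || any(cfg$histo_spacing <= 0))
    stopf("spacings must be > 0")
  has_tumor <- all(cfg$tumor_axes > 0)
  if (any(cfg$tumor_axes < 0)) stopf("tumor half-axes must be >= 0")
  if (has_tumor) {
    # tumor strictly inside the specimen: check a dense tumor-surface sample
    th <- seq(0, pi, length.out = 25)
    ph <- seq(0, 2 * pi, length.out = 49)[-1]
    S <- cbind(as.vector(outer(sin(th), cos(ph))) * cfg$tumor_axes[1] + cfg$tumor_center[1],
               as.vector(outer(sin(th), sin(ph))) * cfg$tumor_axes[2] + cfg$tumor_center[2],
               as.vector(outer(cos(th), rep(1, length(ph)))) * cfg$tumor_axes[3] + cfg$tumor_center[3])
    spec <- list(a = cfg$half_axes[1], b = cfg$half_axes[2],
                 c = cfg$half_axes[3], m = cfg$exponent)
    if (max(se_implicit(spec, S)) >= 1)
      stopf("tumor is not strictly inside the specimen (implicit value %.3f >= 1)",
            max(se_implicit(spec, S)))
  }
  invisible(cfg)
}

#' Generate a rasterized phantom specimen volume
#'
#' Rasterizes the analytic specimen at the configured US voxel spacing
#' (labels 0/1/2/3) and returns both the volume and the analytic geometry
#' handle used for all ground-truth computations. Fiducial base positions
#' and tilts are drawn deterministically from `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list with elements `volume` (a [label_volume()]) and `geometry`
#'   (the analytic handle, class `phantom_geometry`).
#' @export
generate_specimen <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  a <- config$half_axes[1]; b <- config$half_axes[2]; cc <- config$half_axes[3]
  spec <- list(a = a, b = b, c = cc, m = config$exponent)
  fiducials <- with_seed(config$seed, {
    if (config$n_fiducials == 0) list() else {
      th0 <- stats::runif(1, 0, 2 * pi)
      zs_chk <- seq(-cc, cc, length.out = 81)
      # bases near the central axis so the cannulas traverse (nearly) the
      # whole specimen length before the shrinking cross-section clips
      # them; rigid cannulas cannot cross, so axes are re-drawn until all
      # pairs stay separated over the full length
      fids <- list()
      for (k in seq_len(config$n_fiducials)) {
        tilt_max <- config$fiducial_tilt
        for (try in 1:60) {
          th <- th0 + (k - 1) * 2 * pi / 3 + stats::runif(1, -0.3, 0.3)
          base <- c(0.28 * a * cos(th), 0.22 * b * sin(th))
          tilt <- stats::runif(1, 0.45, 1) * tilt_max * pi / 180
          psi <- stats::runif(1, 0, 2 * pi)
          slope <- c(tan(tilt) * cos(psi), tan(tilt) * sin(psi))
          sep_ok <- all(vapply(fids, function(f) {
            fslope <- f$dir[1:2] / f$dir[3]
            dx <- (base[1] - f$base[1]) + zs_chk * (slope[1] - fslope[1])
            dy <- (base[2] - f$base[2]) + zs_chk * (slope[2] - fslope[2])
            min(sqrt(dx^2 + dy^2)) >= config$fiducial_diameter + 0.6
          }, TRUE))
          if (sep_ok) break
          if (try %% 15 == 0) tilt_max <- tilt_max * 0.6
        }
        dirv <- c(slope, 1)
        fids[[k]] <- list(base = base, dir = dirv / sqrt(sum(dirv^2)),
                          radius = config$fiducial_diameter / 2)
      }
      fids
    }
  })
  tr <- list(s = config$shrinkage, stretch = config$stretch_factor,
             amp = config$deformation_amp,
             wavelengths = c(2 * cc * (1 - config$shrinkage),
                             2 * b * (1 - config$shrinkage),
                             2 * a * (1 - config$shrinkage)),
             phases = with_seed(config$seed + 7L, stats::runif(4, 0, 2 * pi)))
  geom <- structure(list(spec = spec,
                         mucosa = config$mucosa_sector * pi / 180,
                         tumor = list(center = config$tumor_center,
                                      axes = config$tumor_axes),
                         fiducials = fiducials, transform = tr,
                         x_positive = "cranial", config = config),
                    class = "phantom_geometry")

  pad <- 1
  sp <- config$us_spacing
  xs <- seq(-(a + pad), a + pad, by = sp[1])
  ys <- seq(-(b + pad), b + pad, by = sp[2])
  zs <- seq(-(cc + pad), cc + pad, by = sp[3])
  fx <- abs(xs / a)^spec$m; fy <- abs(ys / b)^spec$m; fz <- abs(zs / cc)^spec$m
  impl <- outer(outer(fx, fy, "+"), fz, "+")
  lab <- array(0L, dim(impl))
  inside <- impl <= 1
  lab[inside] <- 1L
  if (all(config$tumor_axes > 0)) {
    tc <- config$tumor_center; ta <- config$tumor_axes
    gx <- ((xs - tc[1]) / ta[1])^2
    gy <- ((ys - tc[2]) / ta[2])^2
    gz <- ((zs - tc[3]) / ta[3])^2
    tin <- outer(outer(gx, gy, "+"), gz, "+") <= 1
    lab[inside & tin] <- 2L
  }
  for (fid in fiducials) {
    X <- xs - fid$base[1]; Y <- ys - fid$base[2]; Z <- zs
    n2 <- outer(outer(X^2, Y^2, "+"), Z^2, "+")
    pr <- outer(outer(X * fid$dir[1], Y * fid$dir[2], "+"), Z * fid$dir[3], "+")
    lab[inside & (n2 - pr^2) <= fid$radius^2] <- 3L
  }
  vol <- label_volume(lab, spacing = sp,
                      origin = c(xs[1], ys[1], zs[1]), validate = FALSE)
  geom$grid <- list(origin = vol$origin, spacing = sp, dim = dim(lab))
  list(volume = vol, geometry = geom)
}

#' Apply the histopathology transform and section the phantom
#'
#' Applies uniform linear shrinkage (1 - s), the optional volume-preserving
#' stretch and smooth in-plane deformation, then sections the transformed
#' specimen along z into `slice_thickness` blocks and rasterizes each
#' block's central plane (a 4 um microtome slide samples one plane of its
#' 4 mm block) into a 2D label mask with fiducial holes and analytic
#' mucosal-edge landmarks. Ground truth on both sides is computed from the
#' continuous geometry.
#'
#' @param geometry the analytic handle from [generate_specimen()].
#' @param config the [phantom_config()]; defaults to the one stored in the
#'   geometry handle.
#' @return list with `stack` (a [slide_stack()]) and `truth` (class
#'   `ground_truth`: per-slide true measurements on both sides, true end
#'   margins, and the true slide-to-US-elevation correspondence).
#' @export
apply_histology_transform <- function(geometry, config = geometry$config) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  tr <- geometry$transform
  sc <- transform_scales(tr)
  cc <- geometry$spec$c
  zh_min <- -cc * sc[3]
  extent <- 2 * cc * sc[3]
  thick <- config$slice_thickness
  n_slides <- ceiling(extent / thick - 1e-9)
  zh <- zh_min + (seq_len(n_slides) - 0.5) * thick
  # the last section is usually only partially filled; its slide samples
  # the center of the remaining tissue, not the (possibly empty) center
  # of a full 4 mm block
  zh[n_slides] <- (zh_min + (n_slides - 1) * thick + zh_min + extent) / 2

  pad <- 0.8 + tr$amp
  xr <- geometry$spec$a * sc[1] + pad
  yr <- geometry$spec$b * sc[2] + pad
  hx <- seq(-xr, xr, by = config$histo_spacing[1])
  hy <- seq(-yr, yr, by = config$histo_spacing[2])
  G <- cbind(rep(hx, times = length(hy)), rep(hy, each = length(hx)))

  slides <- vector("list", n_slides)
  edges <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    Q <- cbind(G, zh[i])
    P <- hist_inverse(tr, Q)
    lab <- label_at_points(geometry, P)
    slides[[i]] <- matrix(lab, nrow = length(hx), ncol = length(hy))
    z_us <- zh[i] / sc[3]
    eb <- se_boundary(geometry$spec, z_us, geometry$mucosa)
    if (!is.null(eb) && any(slides[[i]] > 0L))
      edges[[i]] <- hist_forward(tr, cbind(eb, z_us))[, 1:2, drop = FALSE]
  }

  stack <- slide_stack(slides, spacing = config$histo_spacing,
                       slice_thickness = thick,
                       orientation = list(x_positive = geometry$x_positive),
                       mucosal_edges = edges, origin = c(hx[1], hy[1]),
                       specimen = config$specimen, validate = FALSE)

  truth <- phantom_ground_truth(geometry, zh, sc)
  list(stack = stack, truth = truth)
}

# assemble ground truth from the continuous geometry
phantom_ground_truth <- function(geometry, zh, sc) {
  has_tumor <- all(geometry$tumor$axes > 0)
  zg <- axis_coords(geometry$grid$origin[3], geometry$grid$spacing[3],
                    geometry$grid$dim[3])
  rows_us <- list(); rows_h <- list()
  corr <- data.frame(slide = seq_along(zh), z_us = zh / sc[3],
                     index = vapply(zh / sc[3],
                                    function(z) which.min(abs(zg - z)), 1L))
  if (has_tumor) {
    for (i in seq_along(zh)) {
      z_us <- zh[i] / sc[3]
      su <- slice_truth(geometry, z_us, "US")
      if (is.null(su)) next
      sh <- slice_truth(geometry, z_us, "histology")
      rows_us[[length(rows_us) + 1]] <-
        data.frame(slide = i, z_us = z_us, TT = su$TT, cranial = su$cranial,
                   deep = su$deep, caudal = su$caudal)
      rows_h[[length(rows_h) + 1]] <-
        data.frame(slide = i, z_h = zh[i], TT = sh$TT, cranial = sh$cranial,
                   deep = sh$deep, caudal = sh$caudal)
    }
  }
  us <- if (length(rows_us)) do.call(rbind, rows_us) else NULL
  hh <- if (length(rows_h)) do.call(rbind, rows_h) else NULL
  ends_us <- if (has_tumor) end_margins_truth_us(geometry) else c(anterior = NA, posterior = NA)
  ends_h <- if (has_tumor) {
    tz <- geometry$tumor$center[3]; ta <- geometry$tumor$axes[3]
    cc <- geometry$spec$c
    c(anterior = ((tz - ta) + cc) * sc[3], posterior = ((cc - (tz + ta))) * sc[3])
  } else c(anterior = NA, posterior = NA)
  structure(list(us = us, histo = hh, ends_us = ends_us, ends_histo = ends_h,
                 correspondence = corr, scales = sc,
                 specimen = geometry$config$specimen),
            class = "ground_truth")
}

#' Analytic ground-truth measurements as a measurement record
#'
#' Emits the phantom's continuous-geometry measurements in the same record
#' schema the measurement pipeline produces, for use as an oracle.
#'
#' @param truth a `ground_truth` from [apply_histology_transform()].
#' @param side `"US"` or `"histology"`.
#' @return a [measurement_record()].
#' @export
true_measurements <- function(truth, side = c("US", "histology")) {
  side <- match.arg(side)
  tab <- if (side == "US") truth$us else truth$histo
  ends <- if (side == "US") truth$ends_us else truth$ends_histo
  measurement_record(truth$specimen,
                     if (side == "US") "US-manual" else "histology",
                     slice = tab, anterior = unname(ends["anterior"]),
                     posterior = unname(ends["posterior"]))
}

#' Analytic mucosal-edge landmarks for US slices
#'
#' Per US elevation index within the specimen extent, the two boundary
#' points where the mucosal sector meets the resection surface on that
#' slice, in world mm. This is the input a human observer supplies in the
#' clinical workflow; the phantom emits it analytically.
#'
#' @param geometry a `phantom_geometry`.
#' @return data.frame with columns `index`, `x1`, `y1`, `x2`, `y2`.
#' @export
us_landmarks <- function(geometry) {
  zg <- axis_coords(geometry$grid$origin[3], geometry$grid$spacing[3],
                    geometry$grid$dim[3])
  rows <- lapply(seq_along(zg), function(i) {
    eb <- se_boundary(geometry$spec, zg[i], geometry$mucosa)
    if (is.null(eb)) return(NULL)
    data.frame(index = i, x1 = eb[1, 1], y1 = eb[1, 2],
               x2 = eb[2, 1], y2 = eb[2, 2])
  })
  do.call(rbind, rows)
}
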