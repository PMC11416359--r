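# Slide-to-US-slice correspondence, reproducing the study's two-step
# matching: (1) divide the annotated specimen length by the number of 4 mm
# slices to get nominal positions; (2) refine each slide within a window
# using the linearity of inter-fiducial distances. The study's final
# manual visual check is replaced by a reported residual score plus a
# monotonicity constraint solved exactly by dynamic programming.

#' Nominal slide-center positions along the US elevation axis
#'
#' The annotated specimen length L along z is divided by the number of
#' histology slices M; slide i is nominally centered at
#' `z_min + (i - 0.5) * L / M`.
#'
#' @param us_volume a [label_volume()] with specimen voxels.
#' @param M number of histology slices (>= 1).
#' @return numeric vector of M slide-center z positions, mm.
#' @export
nominal_positions <- function(us_volume, M) {
  if (M < 1) stopf("M must be >= 1")
  fgz <- apply(us_volume$voxels > 0L, 3, any)
  if (!any(fgz)) stopf("volume contains no specimen voxels")
  zw <- volume_axis(us_volume, 3)
  zmin <- zw[which(fgz)[1]]
  L <- zw[max(which(fgz))] - zmin
  zmin + (seq_len(M) - 0.5) * L / M
}

# fiducial cross-section centroids on one 2D mask, world mm
fiducial_centroids <- function(mask, spacing, origin, min_pixels = 3L) {
  fm <- mask == 3L
  if (!any(fm)) return(NULL)
  lab <- .label_components_2d(fm, 8L)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sizes <- vapply(ids, function(id) sum(lab == id), 1L)
  # components clipped by the specimen boundary have biased centroids;
  # drop any much smaller than the largest cross-section in the plane
  keep <- sizes >= min_pixels & sizes >= 0.5 * max(sizes)
  ids <- ids[keep]
  cen <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    colMeans(pixel_world(idx, spacing, origin))
  })
  cen <- do.call(rbind, cen)
  if (is.null(cen) || nrow(cen) < 1) return(NULL)
  cen
}

sorted_pair_distances <- function(cen) {
  if (is.null(cen) || nrow(cen) < 2) return(NULL)
  sort(as.vector(stats::dist(cen)), decreasing = TRUE)
}

#' Inter-fiducial distance profile
#'
#' For a volume: per elevation index, the pairwise distances between
#' fiducial cross-section centroids, sorted descending so the profile is
#' invariant to fiducial relabeling. For a slide stack: the same per
#' slide, from the fiducial holes. Planes/slides with fewer than two
#' fiducial components get a NULL entry (profile unavailable; matching
#' falls back to nominal positions there, as in the study's specimens
#' where the cannulas were not visible).
#'
#' @param x a [label_volume()] or [slide_stack()].
#' @return object of class `fiducial_profile`: list with `distances` (one
#'   sorted vector or NULL per plane/slide) and `available`.
#' @export
fiducial_profile <- function(x) {
  if (inherits(x, "label_volume")) {
    n <- dim(x$voxels)[3]
    dists <- lapply(seq_len(n), function(iz)
      sorted_pair_distances(fiducial_centroids(x$voxels[, , iz],
                                               x$spacing[1:2], x$origin[1:2])))
    z <- volume_axis(x, 3)
  } else if (inherits(x, "slide_stack")) {
    dists <- lapply(x$slides, function(m)
      sorted_pair_distances(fiducial_centroids(m, x$spacing, x$origin)))
    z <- slide_centers(x)
  } else stopf("fiducial_profile needs a label_volume or slide_stack")
  structure(list(distances = dists, z = z,
                 available = !vapply(dists, is.null, TRUE)),
            class = "fiducial_profile")
}

# RMS mismatch between two sorted distance tuples. Tuples of unequal
# length (a fiducial clipped away on one side) compare different pairs
# after sorting, so rank-wise comparison is invalid; each distance in the
# shorter tuple is matched to its nearest partner in the longer one, and
# a mild penalty per missing component keeps full-count planes preferred.
profile_residual <- function(us_d, h_d, alpha) {
  hs <- alpha * h_d
  if (length(us_d) == length(hs)) return(sqrt(mean((us_d - hs)^2)))
  if (length(us_d) < length(hs)) { a <- us_d; b <- hs } else { a <- hs; b <- us_d }
  sqrt(mean(vapply(a, function(v) min((v - b)^2), 0.0))) +
    0.04 * (length(b) - length(a))
}

#' Match histology slides to US elevation slices
#'
#' Two-step matching: nominal positions from the length-division rule,
#' then within `+- window` of each nominal position the US slice
#' minimizing the fiducial-profile residual. Histology distances are first
#' rescaled by the ratio of mean profiles (global scale compensation:
#' fixation shrinks histology distances relative to US, and without
#' compensation shrinkage dominates the residual). Matched indices are
#' constrained to be strictly increasing with slide order; the constrained
#' optimum is found by dynamic programming. Residuals are reported, never
#' thresholded — the study's manual visual inspection becomes a
#' human-reviewable score.
#'
#' @param us_volume a [label_volume()].
#' @param stack the [slide_stack()] of the same specimen.
#' @param window search half-window in mm around each nominal position
#'   (default 4, one slice thickness: sectioning uncertainty is at most
#'   one slice).
#' @return object of class `slice_correspondence`: per-slide matched
#'   index, z, residual and search window, plus L, M and the scale factor
#'   used.
#' @export
match_slides <- function(us_volume, stack, window = 4) {
  if (!length(stack$slides)) stopf("empty slide stack")
  if (window <= 0) stopf("window must be > 0")
  M <- length(stack$slides)
  nom <- nominal_positions(us_volume, M)
  zw <- volume_axis(us_volume, 3)
  fgz <- which(apply(us_volume$voxels > 0L, 3, any))

  # Initial search-window centers: the L/M division assumes the M slices
  # exactly tile the specimen, but the last section is only partially
  # filled (on average half), so L/M under-estimates the true section
  # spacing; spacing L/(M - 0.5) anchored at the anterior extent is the
  # better first guess. The reported nominal positions stay the plain
  # L/M rule.
  zmin_fg <- zw[min(fgz)]
  zmax_fg <- zw[max(fgz)]
  ctr <- if (M == 1) nom else
    zmin_fg + (seq_len(M) - 0.5) * (zmax_fg - zmin_fg) / (M - 0.5)

  up <- fiducial_profile(us_volume)
  hp <- fiducial_profile(stack)
  usable <- any(up$available[fgz]) && any(hp$available)
  # without any usable fiducials the matcher reduces to the plain
  # nominal-position rule
  if (!usable) ctr <- nom

  # least-squares US/histology scale from the profiles at given plane
  # positions (restricted to planes with matching component counts)
  alpha_at <- function(ctr) {
    num <- 0; den <- 0
    for (i in seq_len(M)) {
      if (!hp$available[i]) next
      iz <- which.min(abs(zw - ctr[i]))
      if (!up$available[iz]) next
      if (length(up$distances[[iz]]) != length(hp$distances[[i]])) next
      num <- num + sum(up$distances[[iz]] * hp$distances[[i]])
      den <- den + sum(hp$distances[[i]]^2)
    }
    if (den > 0) num / den else
      mean(unlist(up$distances[fgz])) / mean(unlist(hp$distances))
  }
  alpha <- if (usable) alpha_at(ctr) else NA_real_

  make_cand <- function(ctr) lapply(seq_len(M), function(i) {
    ks <- which(abs(zw - ctr[i]) <= window + 1e-9)
    ks <- intersect(ks, seq(min(fgz), max(fgz)))
    if (!length(ks)) ks <- which.min(abs(zw - ctr[i]))
    ks
  })
  make_cost <- function(cand, ctr, alpha) lapply(seq_len(M), function(i) {
    ks <- cand[[i]]
    res <- rep(NA_real_, length(ks))
    if (usable && hp$available[i]) {
      for (j in seq_along(ks)) {
        if (up$available[ks[j]])
          res[j] <- profile_residual(up$distances[[ks[j]]],
                                     hp$distances[[i]], alpha)
      }
    }
    # A candidate plane without a usable US profile is penalized (not
    # free) when the slide itself has holes, so residual-less planes
    # cannot undercut genuine matches; if the slide has no holes every
    # candidate carries only the center pull.
    base <- if (usable && hp$available[i]) ifelse(is.na(res), 1.0, res)
    else rep(0, length(ks))
    list(res = res, c = base + 0.005 * abs(zw[ks] - ctr[i]))
  })

  # DP over (slide, candidate) minimizing residual cost plus an
  # equal-spacing penalty on consecutive matches (sections are equally
  # cut, so consecutive section centers should be one estimated spacing
  # apart), subject to strictly increasing indices. Near-degenerate
  # fiducial geometry (flat residual in z) is then regularized by the
  # spacing prior instead of wandering across the window. The last
  # transition is left unpenalized: the partial last section has its own,
  # shorter spacing.
  INF <- 1e18
  run_dp <- function(cand, cost, spacing_est, mu) {
    dp <- vector("list", M)
    prev <- vector("list", M)
    dp[[1]] <- cost[[1]]$c
    prev[[1]] <- rep(0L, length(cand[[1]]))
    for (i in seq_len(M)[-1]) {
      ki <- cand[[i]]
      kp <- cand[[i - 1]]
      dp[[i]] <- rep(INF, length(ki))
      prev[[i]] <- rep(0L, length(ki))
      mui <- if (i == M) 0 else mu
      for (j in seq_along(ki)) {
        ok <- which(kp < ki[j])
        if (!length(ok)) next
        tot <- dp[[i - 1]][ok] +
          mui * abs((zw[ki[j]] - zw[kp[ok]]) - spacing_est)
        best <- which.min(tot)
        if (tot[best] < INF) {
          dp[[i]][j] <- tot[best] + cost[[i]]$c[j]
          prev[[i]][j] <- ok[best]
        }
      }
    }
    if (all(dp[[M]] >= INF)) {
      bad <- which(vapply(seq_len(M), function(i) all(dp[[i]] >= INF), TRUE))
      stopf("monotone matching unattainable within windows (conflicting slides: %s)",
            paste(bad, collapse = ", "))
    }
    sel <- integer(M)
    sel[M] <- which.min(dp[[M]])
    if (M > 1) for (i in rev(seq_len(M - 1))) sel[i] <- prev[[i + 1]][sel[i + 1]]
    sel
  }

  # Self-consistent refinement. Pass 0 uses the geometric first guess
  # with a weak spacing prior. Each refinement then (a) re-estimates the
  # US/histology scale on the matched planes (the initial ratio of mean
  # profiles is biased when fiducial visibility is asymmetric along z),
  # (b) fits the straight line z = A + B * slide through the
  # residual-matched slides — B is the section spacing as seen in the US
  # frame — and re-centers windows and the spacing prior on that line
  # (the last slide is centered on the remaining tissue, since its
  # section is partially filled), and re-runs the assignment with the
  # full prior weight.
  cand <- make_cand(ctr)
  cost <- make_cost(cand, ctr, alpha)
  spacing_est <- if (M > 1) (zmax_fg - zmin_fg) / (M - 0.5) else 0
  sel <- run_dp(cand, cost, spacing_est, mu = if (usable) 0.005 else 0)
  if (usable && M > 1) {
    for (pass in 1:2) {
      matched <- rep(FALSE, M)
      for (i in seq_len(M)) {
        if (!hp$available[i]) next
        iz <- cand[[i]][sel[i]]
        matched[i] <- up$available[iz] &&
          length(up$distances[[iz]]) == length(hp$distances[[i]])
      }
      # section spacing B from the matched slides (robust median of
      # consecutive differences); the intercept is anchored geometrically:
      # sectioning starts at the anterior cap, so slide 1 is centered half
      # a section spacing past the anterior extent. This breaks the
      # degeneracy between a global match offset and the scale alpha.
      fit_on <- which(matched & (seq_len(M) < M | sum(matched[-M]) < 2))
      if (length(fit_on) >= 2) {
        zi <- vapply(fit_on, function(i) zw[cand[[i]][sel[i]]], 0.0)
        spacing_est <- stats::median(diff(zi) / diff(fit_on))
      }
      ctr <- zmin_fg + (seq_len(M) - 0.5) * spacing_est
      ctr[M] <- (zmin_fg + (M - 1) * spacing_est + zmax_fg) / 2
      ctr <- pmin(pmax(ctr, zmin_fg), zmax_fg)
      # scale from the profiles at the anchored positions (matched planes
      # would feed a drifted offset back into alpha)
      alpha <- alpha_at(ctr)
      cand <- make_cand(ctr)
      cost <- make_cost(cand, ctr, alpha)
      sel <- run_dp(cand, cost, spacing_est, mu = 0.03)
    }
  }
  idx <- vapply(seq_len(M), function(i) cand[[i]][sel[i]], 1L)
  res <- vapply(seq_len(M), function(i) cost[[i]]$res[sel[i]], 1.0)

  # Slides without a usable residual (fiducials not visible there, as in
  # some of the study's slices) are re-placed on the refined line (the
  # automated analogue of a human extrapolating from confident matches),
  # keeping indices strictly monotone.
  good <- !is.na(res)
  if (usable && sum(good) >= 2 && any(!good)) {
    for (i in which(!good)) {
      lo <- if (i > 1) idx[i - 1] + 1L else 1L
      nxt <- which(good & seq_len(M) > i)
      hi <- if (length(nxt)) idx[min(nxt)] - (min(nxt) - i) else length(zw)
      ks <- cand[[i]]
      ks <- ks[ks >= lo & ks <= hi]
      if (length(ks)) idx[i] <- ks[which.min(abs(zw[ks] - ctr[i]))]
    }
  }

  fgzw <- zw[fgz]
  structure(list(specimen = stack$specimen,
                 L = max(fgzw) - min(fgzw), M = M, window = window,
                 scale = alpha, fiducials_used = usable,
                 slides = data.frame(slide = seq_len(M), nominal_z = nom,
                                     index = idx, z = zw[idx],
                                     residual = res)),
            class = "slice_correspondence")
}

#' @export
print.slice_correspondence <- function(x, ...) {
  cat(sprintf("<slice_correspondence> '%s': %d slides over L = %.1f mm (window +-%g mm, %s)\n",
              x$specimen, x$M, x$L, x$window,
              if (x$fiducials_used) sprintf("fiducial scale %.3f", x$scale)
              else "no fiducials: nominal fallback"))
  print(x$slides, row.names = FALSE)
  invisible(x)
}

#' Write / read a slice correspondence as JSON
#'
#' Schema: `specimen`, `L_mm`, `M`, `window_mm`, `scale`, `fiducials_used`
#' and a `slides` array with `slide`, `nominal_z_mm`, `index` (1-based US
#' elevation index), `z_mm`, `residual_mm` (null where no profile).
#'
#' @param corr a `slice_correspondence`.
#' @param path JSON path.
#' @return the path (write) / a `slice_correspondence` (read).
#' @export
write_correspondence <- function(corr, path) {
  jsonlite::write_json(
    list(specimen = corr$specimen, L_mm = corr$L, M = corr$M,
         window_mm = corr$window, scale = corr$scale,
         fiducials_used = corr$fiducials_used,
         slides = lapply(seq_len(nrow(corr$slides)), function(i)
           list(slide = corr$slides$slide[i],
                nominal_z_mm = corr$slides$nominal_z[i],
                index = corr$slides$index[i], z_mm = corr$slides$z[i],
                residual_mm = if (is.na(corr$slides$residual[i])) NULL
                else corr$slides$residual[i]))),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_correspondence
#' @export
read_correspondence <- function(path) {
  m <- jsonlite::read_json(path)
  slides <- do.call(rbind, lapply(m$slides, function(s)
    data.frame(slide = s$slide, nominal_z = s$nominal_z_mm, index = s$index,
               z = s$z_mm,
               residual = if (is.null(s$residual_mm)) NA_real_ else s$residual_mm)))
  structure(list(specimen = m$specimen, L = m$L_mm, M = m$M,
                 window = m$window_mm,
                 scale = if (is.null(m$scale)) NA_real_ else m$scale,
                 fiducials_used = isTRUE(m$fiducials_used), slides = slides),
            class = "slice_correspondence")
}
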