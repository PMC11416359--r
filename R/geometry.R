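# Analytic specimen geometry: a superellipsoid specimen with a mucosal
# sector, an embedded ellipsoidal tumor, and up to three tilted cylindrical
# fiducial channels. All ground-truth distances are computed on this
# continuous geometry (sub-voxel), never on rasterized grids.

# superellipsoid implicit value |x/a|^m + |y/b|^m + |z/c|^m at points P (n x 3)
se_implicit <- function(spec, P) {
  abs(P[, 1] / spec$a)^spec$m + abs(P[, 2] / spec$b)^spec$m +
    abs(P[, 3] / spec$c)^spec$m
}

# cross-section half-axes of the superellipsoid at elevation z, or NULL
se_cross_section <- function(spec, z) {
  u <- abs(z / spec$c)^spec$m
  if (u >= 1) return(NULL)
  r <- (1 - u)^(1 / spec$m)
  c(A = spec$a * r, B = spec$b * r)
}

# boundary points of the superellipse cross-section at parameter(s) t
se_boundary <- function(spec, z, t) {
  ab <- se_cross_section(spec, z)
  if (is.null(ab)) return(NULL)
  e <- 2 / spec$m
  cbind(x = ab[1] * sign(cos(t)) * abs(cos(t))^e,
        y = ab[2] * sign(sin(t)) * abs(sin(t))^e)
}

# tumor cross-section ellipse (center, half-axes) at elevation z, or NULL
tumor_cross_section <- function(tumor, z) {
  if (any(tumor$axes <= 0)) return(NULL)
  u <- (z - tumor$center[3]) / tumor$axes[3]
  if (abs(u) >= 1) return(NULL)
  rho <- sqrt(1 - u^2)
  list(center = tumor$center[1:2], axes = tumor$axes[1:2] * rho)
}

# Minimum distance from points P (n x d) to an axis-aligned ellipse (d = 2)
# or ellipsoid (d = 3), vectorized bisection on the KKT parameter.
# Points inside the ellipse get distance 0 (not needed here, but safe).
dist_point_ellipsoid <- function(P, center, axes) {
  P <- matrix(P, ncol = length(axes))
  U <- abs(sweep(P, 2, center))
  inside <- rowSums(sweep(U, 2, axes, "/")^2) <= 1
  d <- numeric(nrow(P))
  out <- which(!inside)
  if (length(out)) {
    Uo <- U[out, , drop = FALSE]
    amax <- max(axes)
    nrm <- sqrt(rowSums(Uo^2))
    lo <- rep(0, length(out))
    hi <- 2 * amax * nrm + amax^2
    AU <- sweep(Uo, 2, axes, "*")
    for (iter in 1:100) {
      mid <- (lo + hi) / 2
      f <- rowSums((AU / outer(mid, axes^2, "+"))^2) - 1
      hi <- ifelse(f < 0, mid, hi)
      lo <- ifelse(f >= 0, mid, lo)
    }
    t_ <- (lo + hi) / 2
    X <- Uo * outer(rep(1, length(out)), axes^2) / outer(t_, axes^2, "+")
    d[out] <- sqrt(rowSums((Uo - X)^2))
  }
  d
}

## ---- histology transform -------------------------------------------------

# Scale factors US -> histology: uniform linear shrinkage (1 - s) on all
# axes; the stretch factor F (pinned-out specimen) is volume-preserving:
# z x F, in-plane x F^(-1/2).
transform_scales <- function(tr) {
  sxy <- (1 - tr$s) / sqrt(tr$stretch)
  sz <- (1 - tr$s) * tr$stretch
  c(sxy, sxy, sz)
}

# smooth low-frequency in-plane displacement, defined in histology space
deform_field <- function(tr, Q) {
  if (tr$amp <= 0) return(matrix(0, nrow(Q), 2))
  w <- tr$wavelengths
  ph <- tr$phases
  dx <- tr$amp * sin(2 * pi * Q[, 3] / w[1] + ph[1]) *
    cos(pi * Q[, 2] / w[2] + ph[2])
  dy <- tr$amp * sin(2 * pi * Q[, 3] / w[1] + ph[3]) *
    cos(pi * Q[, 1] / w[3] + ph[4])
  cbind(dx, dy)
}

# histology world point -> US world point (exact inverse)
hist_inverse <- function(tr, Q) {
  Q <- matrix(Q, ncol = 3)
  D <- deform_field(tr, Q)
  sc <- transform_scales(tr)
  cbind((Q[, 1] - D[, 1]) / sc[1], (Q[, 2] - D[, 2]) / sc[2], Q[, 3] / sc[3])
}

# US world point -> histology world point (fixed point when deformed)
hist_forward <- function(tr, P) {
  P <- matrix(P, ncol = 3)
  sc <- transform_scales(tr)
  Q0 <- sweep(P, 2, sc, "*")
  if (tr$amp <= 0) return(Q0)
  Q <- Q0
  for (i in 1:12) {
    D <- deform_field(tr, Q)
    Q <- Q0 + cbind(D, 0)
  }
  Q
}

## ---- label evaluation ----------------------------------------------------

# squared perpendicular distance from points P (n x 3) to a fiducial axis
fiducial_perp2 <- function(fid, P) {
  v1 <- P[, 1] - fid$base[1]
  v2 <- P[, 2] - fid$base[2]
  v3 <- P[, 3]
  proj <- v1 * fid$dir[1] + v2 * fid$dir[2] + v3 * fid$dir[3]
  v1^2 + v2^2 + v3^2 - proj^2
}

# semantic label (0/1/2/3) of arbitrary US-space points, fiducial > tumor >
# specimen priority
label_at_points <- function(geom, P) {
  P <- matrix(P, ncol = 3)
  lab <- integer(nrow(P))
  inside <- se_implicit(geom$spec, P) <= 1
  lab[inside] <- 1L
  tm <- geom$tumor
  if (all(tm$axes > 0)) {
    tv <- rowSums(sweep(sweep(P, 2, tm$center), 2, tm$axes, "/")^2)
    lab[inside & tv <= 1] <- 2L
  }
  for (fid in geom$fiducials) {
    lab[inside & fiducial_perp2(fid, P) <= fid$radius^2] <- 3L
  }
  lab
}

## ---- region geometry (shared by analytic truth and pixel partition) ------

# Chord frame on a slice: midpoint of the mucosal chord, unit chord
# direction u, and unit into-tissue normal w (chosen to point toward the
# tissue reference point, typically the tissue centroid).
chord_frame <- function(e1, e2, toward) {
  u <- e2 - e1
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stopf("mucosal edge points coincide")
  u <- u / nu
  w <- c(-u[2], u[1])
  m <- (e1 + e2) / 2
  if (sum((toward - m) * w) < 0) w <- -w
  list(mid = m, u = u, w = w)
}

# Assign points to mucosal / cranial / deep / caudal. Points on the mucosal
# side of the chord (dn <= 0) form the mucosal arc; the rest is split by
# angular position against the two rays at +-45 degrees from the chord
# midpoint, measured in physical mm so anisotropic pixels cannot distort
# the angle. `x_positive` names the anatomical direction of increasing x.
region_of_points <- function(P, frame, x_positive) {
  P <- matrix(P, ncol = 2)
  dn <- (P[, 1] - frame$mid[1]) * frame$w[1] + (P[, 2] - frame$mid[2]) * frame$w[2]
  du <- (P[, 1] - frame$mid[1]) * frame$u[1] + (P[, 2] - frame$mid[2]) * frame$u[2]
  gam <- atan2(du, dn)
  pos_is_xpos <- frame$u[1] > 0 || (frame$u[1] == 0 && frame$u[2] > 0)
  other <- if (x_positive == "cranial") "caudal" else "cranial"
  pos_lab <- if (pos_is_xpos) x_positive else other
  neg_lab <- if (pos_is_xpos) other else x_positive
  out <- rep("deep", nrow(P))
  out[gam > pi / 4] <- pos_lab
  out[gam < -pi / 4] <- neg_lab
  out[dn <= 0] <- "mucosal"
  out
}

## ---- analytic slice truth ------------------------------------------------

# Ground-truth slice measurements at US-space elevation z_us. side =
# "US" measures the undeformed geometry; side = "histology" maps the
# section through the histology transform first. Returns NULL when the
# tumor does not reach this plane.
slice_truth <- function(geom, z_us, side = c("US", "histology"),
                        n_boundary = 3000, n_tumor = 900) {
  side <- match.arg(side)
  tcs <- tumor_cross_section(geom$tumor, z_us)
  if (is.null(tcs)) return(NULL)
  scs <- se_cross_section(geom$spec, z_us)
  if (is.null(scs)) return(NULL)
  t12 <- geom$mucosa
  edges <- se_boundary(geom$spec, z_us, t12)

  # dense non-mucosal boundary samples (parameter t outside [t1, t2])
  tt <- seq(t12[2], t12[1] + 2 * pi, length.out = n_boundary + 1)[-1]
  B <- se_boundary(geom$spec, z_us, tt)

  if (side == "histology") {
    tr <- geom$transform
    map2 <- function(XY) hist_forward(tr, cbind(XY, z_us))[, 1:2, drop = FALSE]
    edges <- map2(edges)
    B <- map2(B)
    tb <- seq(0, 2 * pi, length.out = n_tumor + 1)[-1]
    Tm <- cbind(tcs$center[1] + tcs$axes[1] * cos(tb),
                tcs$center[2] + tcs$axes[2] * sin(tb))
    Tm <- map2(Tm)
    tumor_ref <- colMeans(Tm)
    frame <- chord_frame(edges[1, ], edges[2, ], toward = tumor_ref)
    proj <- (Tm[, 1] - frame$mid[1]) * frame$w[1] +
      (Tm[, 2] - frame$mid[2]) * frame$w[2]
    TT <- max(proj) - min(proj)
    dist_to_tumor <- function(S) {
      if (!nrow(S)) return(NA_real_)
      mind <- Inf
      for (start in seq(1, nrow(S), by = 2000)) {
        blk <- S[start:min(start + 1999, nrow(S)), , drop = FALSE]
        d2 <- outer(blk[, 1], Tm[, 1], "-")^2 + outer(blk[, 2], Tm[, 2], "-")^2
        mind <- min(mind, min(d2))
      }
      sqrt(mind)
    }
  } else {
    frame <- chord_frame(edges[1, ], edges[2, ], toward = tcs$center)
    TT <- 2 * sqrt((tcs$axes[1] * frame$w[1])^2 + (tcs$axes[2] * frame$w[2])^2)
    dist_to_tumor <- function(S) {
      if (!nrow(S)) return(NA_real_)
      min(dist_point_ellipsoid(S, tcs$center, tcs$axes))
    }
  }

  reg <- region_of_points(B, frame, geom$x_positive)
  margins <- vapply(c("cranial", "deep", "caudal"), function(r)
    dist_to_tumor(B[reg == r, , drop = FALSE]), 0.0)
  list(TT = TT, cranial = margins[["cranial"]], deep = margins[["deep"]],
       caudal = margins[["caudal"]], edges = edges, frame = frame)
}

# Ground-truth end margins on the US side: z-distance from the tumor
# extent to the specimen's z extent (the construct both modalities
# measure; see end_margins_us).
end_margins_truth_us <- function(geom) {
  tm <- geom$tumor
  if (any(tm$axes <= 0)) stopf("no tumor in phantom geometry")
  c(anterior = (tm$center[3] - tm$axes[3]) + geom$spec$c,
    posterior = geom$spec$c - (tm$center[3] + tm$axes[3]))
}
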