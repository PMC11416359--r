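# Independent brute-force oracles. These deliberately avoid the package's
# distance-transform code path: distances are minimized over all explicit
# pixel/voxel pairs, with the floating-point expression written to match
# the (y-term + x-term) accumulation order of the separable transform so
# equality can be asserted exactly.

brute_region_margin <- function(mask, part, region, spacing) {
  tum <- which(mask == 2L, arr.ind = TRUE)
  surf <- part$boundary[part$region == region, , drop = FALSE]
  if (!nrow(surf)) return(NA_real_)
  sx2 <- spacing[1] * spacing[1]
  sy2 <- spacing[2] * spacing[2]
  best <- Inf
  for (k in seq_len(nrow(surf))) {
    di <- tum[, 1] - surf[k, 1]
    dj <- tum[, 2] - surf[k, 2]
    best <- min(best, min(sy2 * dj * dj + sx2 * di * di))
  }
  sqrt(best)
}

brute_tumor_thickness <- function(mask, part, spacing, origin) {
  tum <- which(mask == 2L, arr.ind = TRUE)
  w <- part$frame$w
  pr <- apply(tum, 1, function(ij) {
    p <- c(origin[1] + (ij[1] - 1) * spacing[1],
           origin[2] + (ij[2] - 1) * spacing[2])
    (p[1] - part$frame$mid[1]) * w[1] + (p[2] - part$frame$mid[2]) * w[2]
  })
  max(pr) - min(pr)
}

brute_end_margins_us <- function(volume) {
  zw <- volume$origin[3] + (seq_len(dim(volume$voxels)[3]) - 1) * volume$spacing[3]
  fgk <- tumk <- c()
  for (k in seq_len(dim(volume$voxels)[3])) {
    sl <- volume$voxels[, , k]
    if (any(sl > 0L)) fgk <- c(fgk, k)
    if (any(sl == 2L)) tumk <- c(tumk, k)
  }
  c(anterior = zw[min(tumk)] - zw[min(fgk)],
    posterior = zw[max(fgk)] - zw[max(tumk)])
}

# Spearman coefficient by the textbook rank formula with average ranks
hand_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# tiny synthetic measurement record builder
toy_record <- function(specimen, modality, slides, vals, anterior = NA, posterior = NA) {
  slice <- NULL
  if (length(slides))
    slice <- data.frame(slide = slides, TT = vals, cranial = vals + 1,
                        deep = vals + 2, caudal = vals + 3)
  measurement_record(specimen, modality, slice = slice,
                     anterior = anterior, posterior = posterior)
}
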