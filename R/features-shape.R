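#' Shape features of a tumour mask
#'
#' Nine morphological descriptors in physical units: voxel count, volume,
#' surface area (exposed-voxel-face counting, which is exact for the
#' digitized shape but overestimates the area of smooth bodies), surface to
#' volume ratio, maximum diameter (largest voxel-centre pairwise distance),
#' minimum diameter (smallest principal-axis extent, taken as
#' \eqn{2\sqrt{3\lambda_{min}}} with \eqn{\lambda_{min}} the smallest
#' eigenvalue of the voxel-centre covariance; for a solid of uniform density
#' this equals the exact axis length of a matching box), compactness
#' \eqn{V/(\sqrt{\pi}A^{3/2})}, spherical disproportion \eqn{A/(4\pi R^2)}
#' with \eqn{R = (3V/4\pi)^{1/3}}, and sphericity
#' \eqn{\pi^{1/3}(6V)^{2/3}/A}.
#'
#' @param mask a non-empty [tumor_mask()].
#' @param spacing optional spacing override (mm); defaults to the mask's.
#' @return Named numeric vector of 9 features, names prefixed `shape__`.
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "tumor_mask"))
  m <- mask$volume$data == 1
  if (!any(m)) stop("shape_features: empty mask", call. = FALSE)
  sp <- if (is.null(spacing)) mask$volume$spacing else as.numeric(spacing)
  shp <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  vvol <- prod(sp)
  V <- n * vvol

  # exposed faces per axis
  A <- 0
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, a] <- nb[, a] + s
      outside <- nb[, a] < 1 | nb[, a] > shp[a]
      inmask <- logical(n)
      inmask[!outside] <- m[nb[!outside, , drop = FALSE]]
      A <- A + sum(!inmask) * face_area[a]
    }
  }

  ctr <- sweep(idx - 1, 2L, sp, `*`)               # physical voxel centres
  max_diam <- if (n == 1L) 0 else {
    pts <- if (n > 2000L) ctr[.boundary_voxels(m, idx), , drop = FALSE] else ctr
    max(stats::dist(pts))
  }
  min_diam <- if (n == 1L) 0 else {
    cv <- stats::cov(ctr) * (n - 1) / n            # population covariance
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    2 * sqrt(3 * max(min(ev), 0))
  }

  R <- (3 * V / (4 * pi))^(1 / 3)
  c(shape__n_voxels = n,
    shape__volume = V,
    shape__surface_area = A,
    shape__surface_volume_ratio = A / V,
    shape__max_diameter = max_diam,
    shape__min_diameter = min_diam,
    shape__compactness = V / (sqrt(pi) * A^1.5),
    shape__spherical_disproportion = A / (4 * pi * R^2),
    shape__sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A)
}

# voxels with at least one exposed face (6-neighbourhood); the maximum
# pairwise distance is attained on this subset
.boundary_voxels <- function(m, idx) {
  shp <- dim(m)
  n <- nrow(idx)
  exposed <- logical(n)
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, a] <- nb[, a] + s
      outside <- nb[, a] < 1 | nb[, a] > shp[a]
      inmask <- logical(n)
      inmask[!outside] <- m[nb[!outside, , drop = FALSE]]
      exposed <- exposed | !inmask
    }
  }
  which(exposed)
}
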