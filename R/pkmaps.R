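#' Bundle of pharmacokinetic maps
#'
#' Holds the five voxelwise maps produced by [compute_pk_maps()]: ktrans
#' (1/min), kep (1/min), ve (dimensionless), iauc (mM s) and r1 (1/s), all
#' sharing one geometry. Voxels outside the fitted region or flagged invalid
#' are `NA`.
#'
#' @param ktrans,kep,ve,iauc,r1 [image_volume()]s sharing shape and spacing.
#' @return An object of class `pk_maps`.
#' @export
pk_maps <- function(ktrans, kep, ve, iauc, r1) {
  vols <- list(ktrans = ktrans, kep = kep, ve = ve, iauc = iauc, r1 = r1)
  for (nm in names(vols)) {
    stopifnot(inherits(vols[[nm]], "image_volume"))
    stopifnot_same_geometry(ktrans, vols[[nm]], paste0("pk maps (", nm, ")"))
    if (any(vols[[nm]]$data < 0, na.rm = TRUE))
      stop("pk_maps: map `", nm, "` has negative values", call. = FALSE)
  }
  structure(vols, class = "pk_maps")
}

#' @export
print.pk_maps <- function(x, ...) {
  cat("<pk_maps> ", paste(dim(x$ktrans$data), collapse = " x "),
      " voxels; ", sum(is.finite(x$ktrans$data)), " fitted\n", sep = "")
  invisible(x)
}

#' Compute voxelwise pharmacokinetic maps
#'
#' Full per-voxel chain inside a region of interest: R1/M0 from the
#' variable-flip-angle volumes ([fit_vfa_r1()]), dynamic signal to
#' concentration by SPGR inversion ([signal_to_concentration()]), standard
#' Tofts fit ([fit_tofts()]) and initial area under the curve
#' ([compute_iauc()]). Voxels outside the ROI, or whose R1 fit is invalid,
#' are missing in all maps.
#'
#' @param series a [dynamic_series()].
#' @param vfa_volumes list of [image_volume()]s, one per flip angle, on the
#'   same grid as `series`.
#' @param flip_angles flip angles (degrees) matching `vfa_volumes`.
#' @param aif an [aif_model()].
#' @param roi 2x3 matrix (rows lo, hi) of voxel index ranges, or `NULL` for
#'   the whole grid.
#' @param TR repetition time (ms).
#' @param dyn_flip_angle dynamic flip angle (degrees).
#' @param r1_relaxivity contrast relaxivity (1/mM/s).
#' @param iauc_window iAUC window (s).
#' @return A [pk_maps()] bundle on the series geometry.
#' @export
compute_pk_maps <- function(series, vfa_volumes, flip_angles, aif,
                            roi = NULL, TR = 5.3, dyn_flip_angle = 20,
                            r1_relaxivity = 4.5, iauc_window = 60) {
  stopifnot(inherits(series, "dynamic_series"))
  for (v in vfa_volumes)
    stopifnot_same_geometry(series, v, "dynamic series and VFA volumes")
  if (length(vfa_volumes) != length(flip_angles))
    stop("compute_pk_maps: vfa_volumes/flip_angles mismatch", call. = FALSE)

  shp <- dim(series$data)[1:3]
  ord <- order(series$times)
  times <- series$times[ord]

  if (is.null(roi)) roi <- rbind(lo = c(1, 1, 1), hi = shp)
  roi <- as.matrix(roi)
  if (any(roi[1, ] < 1) || any(roi[2, ] > shp) || any(roi[1, ] > roi[2, ]))
    stop("compute_pk_maps: roi outside the grid", call. = FALSE)
  ix <- roi[1, 1]:roi[2, 1]; iy <- roi[1, 2]:roi[2, 2]; iz <- roi[1, 3]:roi[2, 3]
  vox <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  lin <- vox[, 1] + (vox[, 2] - 1) * shp[1] + (vox[, 3] - 1) * shp[1] * shp[2]
  nv <- length(lin)

  # VFA fit
  S_vfa <- matrix(vapply(vfa_volumes, function(v) v$data[lin], numeric(nv)),
                  nrow = nv)
  vfa_fit <- .vfa_fit_matrix(S_vfa, flip_angles, TR)
  ok <- vfa_fit$valid

  # dynamic signal for ROI voxels, phases in time order
  nt <- length(times)
  S_dyn <- matrix(series$data, nrow = prod(shp), ncol = nt)[lin, ord, drop = FALSE]

  ktrans <- kep <- ve <- iauc <- rep(NA_real_, nv)
  if (any(ok)) {
    conc <- .concentration_matrix(S_dyn[ok, , drop = FALSE],
                                  vfa_fit$R1[ok], vfa_fit$M0[ok],
                                  TR, dyn_flip_angle, r1_relaxivity)
    cp <- generate_aif(aif, times)
    fit <- .fit_tofts_matrix(t(conc$ct), cp, times)
    ktrans[ok] <- fit$ktrans
    kep[ok] <- fit$kep
    ve[ok] <- pmin(fit$ve, 1)                      # clip ve to [0, 1]
    # iAUC is a linear functional of the curve: precompute its weights
    w <- vapply(seq_len(nt), function(j) {
      e <- numeric(nt); e[j] <- 1
      compute_iauc(e, times, iauc_window, onset = aif$onset_time)$iauc
    }, numeric(1))
    iauc[ok] <- pmax(as.numeric(conc$ct %*% w), 0)
  }

  to_vol <- function(vals) {
    arr <- array(NA_real_, shp)
    arr[lin] <- vals
    image_volume(arr, spacing = series$spacing, origin = series$origin)
  }
  r1 <- rep(NA_real_, nv)
  r1[ok] <- vfa_fit$R1[ok] * 1000                  # 1/ms -> 1/s
  pk_maps(ktrans = to_vol(ktrans), kep = to_vol(.na_zero_neg(kep)),
          ve = to_vol(ve), iauc = to_vol(iauc), r1 = to_vol(r1))
}

.na_zero_neg <- function(x) {
  x[!is.na(x) & x < 0] <- 0
  x
}
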