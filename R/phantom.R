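#' Digital DCE-MRI phantom specification
#'
#' Defines a spherical lesion on a homogeneous background together with the
#' acquisition emulated by the simulator: a variable-flip-angle SPGR set for
#' T1 mapping and a 60-phase dynamic series at 9 s temporal resolution
#' (TR = 5.3 ms, dynamic flip angle 20 deg), plus auxiliary precontrast
#' (TIRM-like) and delayed postcontrast volumes on their own grids.
#'
#' Default pharmacokinetic truth (ktrans 0.25/min, kep 0.5/min, R1 1/s)
#' produces a lesion whose peak relative enhancement comfortably exceeds the
#' 75% segmentation threshold.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param spacing numeric(3), mm per axis.
#' @param lesion_center voxel index (1-based) of the lesion centre.
#' @param lesion_radius lesion radius in mm.
#' @param true_ktrans,true_kep lesion Tofts parameters (1/min);
#'   requires `true_kep >= true_ktrans > 0` so that ve in (0, 1].
#' @param background_ktrans background transfer constant (1/min).
#' @param true_R1 precontrast relaxation rate (1/s), uniform over the grid.
#' @param M0 equilibrium signal (a.u.).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   per-voxel baseline signal; 0 disables noise.
#' @param times acquisition times (s) of the dynamic phases.
#' @param flip_angles variable flip angles (degrees) for T1 mapping.
#' @param dyn_flip_angle flip angle (degrees) of the dynamic acquisition.
#' @param TR repetition time (ms).
#' @param r1_relaxivity contrast-agent relaxivity (1/mM/s); default 4.5.
#' @param lesion_jitter_sd log-normal sd of optional per-voxel jitter of the
#'   lesion pharmacokinetic parameters (0 = homogeneous lesion).
#' @param aif an [aif_model()]; defaults to the biexponential population AIF
#'   with onset at the end of the first dynamic phase.
#' @param seed integer seed controlling the noise and jitter draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 24), spacing = c(2, 2, 2),
                         lesion_center = NULL, lesion_radius = 12.4,
                         true_ktrans = 0.25, true_kep = 0.5,
                         background_ktrans = 0.02,
                         true_R1 = 1, M0 = 1000, noise_sd = 0.02,
                         times = seq(0, by = 9, length.out = 60),
                         flip_angles = c(2, 5, 8, 12, 15, 20),
                         dyn_flip_angle = 20, TR = 5.3,
                         r1_relaxivity = 4.5, lesion_jitter_sd = 0,
                         aif = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
  if (is.null(aif)) aif <- aif_model(onset_time = times[2])
  if (!(true_kep >= true_ktrans && true_ktrans > 0))
    stop("phantom_spec: need true_kep >= true_ktrans > 0 (ve in (0,1])",
         call. = FALSE)
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  if (background_ktrans < 0)
    stop("phantom_spec: background_ktrans must be >= 0", call. = FALSE)
  ctr_mm <- (lesion_center - 1) * spacing
  lim_mm <- (grid_shape - 1) * spacing
  if (any(ctr_mm - lesion_radius < -spacing / 2) ||
      any(ctr_mm + lesion_radius > lim_mm + spacing / 2))
    stop("phantom_spec: lesion does not fit inside the grid", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 lesion_center = as.numeric(lesion_center),
                 lesion_radius = lesion_radius,
                 true_ktrans = true_ktrans, true_kep = true_kep,
                 background_ktrans = background_ktrans,
                 true_R1 = true_R1, M0 = M0, noise_sd = noise_sd,
                 times = as.numeric(times),
                 flip_angles = as.numeric(flip_angles),
                 dyn_flip_angle = dyn_flip_angle, TR = TR,
                 r1_relaxivity = r1_relaxivity,
                 lesion_jitter_sd = lesion_jitter_sd,
                 aif = aif, seed = as.integer(seed)),
            class = "phantom_spec")
}

# sphere indicator on an axis-aligned grid, by voxel-centre distance
.sphere_mask <- function(shape, spacing, origin, center_mm, radius_mm) {
  cx <- .axis_coords(shape[1], spacing[1], origin[1]) - center_mm[1]
  cy <- .axis_coords(shape[2], spacing[2], origin[2]) - center_mm[2]
  cz <- .axis_coords(shape[3], spacing[3], origin[3]) - center_mm[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  array(d2 <= radius_mm^2, dim = shape)
}

#' Simulate a DCE-MRI phantom
#'
#' Runs the forward physics chain: truth pharmacokinetic maps on a spherical
#' lesion, tissue concentration by the Tofts model driven by the phantom AIF,
#' dynamic SPGR signal through the relaxivity relation
#' \eqn{R_1(t) = R_1(0) + r_1 C_t(t)}, a variable-flip-angle SPGR volume set,
#' and auxiliary TIRM-like (coarser grid) and delayed postcontrast (finer
#' grid) volumes. Gaussian noise with sd `noise_sd * baseline` is added to
#' every simulated signal when `noise_sd > 0`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `dynamic` ([dynamic_series()]), `vfa` (list
#'   of [image_volume()], one per flip angle), `flip_angles`, `tirm`,
#'   `postc` ([image_volume()]s on their own grids), `truth` (list of truth
#'   maps `ktrans`, `kep`, `ve`, `r1` as [image_volume()]s), `mask` (truth
#'   lesion mask), `bbox` (truth bounding box, a 2x3 matrix of voxel index
#'   ranges), and `spec`.
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shp <- spec$grid_shape; sp <- spec$spacing; org <- c(0, 0, 0)
  nvox <- prod(shp)
  ctr_mm <- (spec$lesion_center - 1) * sp

  inside <- .sphere_mask(shp, sp, org, ctr_mm, spec$lesion_radius)
  if (!any(inside))
    stop("simulate_phantom: lesion contains no voxel", call. = FALSE)

  ktrans <- array(spec$background_ktrans, shp)
  kep <- array(spec$true_kep, shp)
  ktrans[inside] <- spec$true_ktrans
  if (spec$lesion_jitter_sd > 0) {
    nles <- sum(inside)
    ktrans[inside] <- ktrans[inside] * exp(stats::rnorm(nles, 0, spec$lesion_jitter_sd))
    kep[inside] <- kep[inside] * exp(stats::rnorm(nles, 0, spec$lesion_jitter_sd))
    # keep ve = ktrans/kep in (0, 1]
    kep <- pmax(kep, ktrans)
  }
  r1_map <- array(spec$true_R1, shp)      # 1/s

  times <- spec$times
  cp <- generate_aif(spec$aif, times)

  # Ct for every voxel: convolution depends on kep only, ktrans scales it.
  # Homogeneous phantoms have very few distinct kep values; exploit that.
  ct <- .ct_matrix(ktrans, kep, cp, times)          # nvox x T

  # dynamic signal
  R1_ms <- spec$true_R1 / 1000                       # 1/ms
  r1x <- spec$r1_relaxivity / 1000                   # 1/mM/ms
  R1_t <- R1_ms + r1x * ct                           # nvox x T
  dyn <- spgr_signal(R1_t, spec$M0, spec$TR, spec$dyn_flip_angle)
  baseline <- dyn[, 1L]
  if (spec$noise_sd > 0)
    dyn <- dyn + stats::rnorm(length(dyn), 0, 1) * (spec$noise_sd * baseline)
  dyn4d <- array(dyn, c(shp, length(times)))

  # variable-flip-angle volumes (precontrast)
  vfa <- lapply(spec$flip_angles, function(a) {
    s <- spgr_signal(array(R1_ms, shp), spec$M0, spec$TR, a)
    if (spec$noise_sd > 0)
      s <- s + array(stats::rnorm(nvox, 0, 1), shp) * (spec$noise_sd * array(baseline, shp))
    image_volume(s, spacing = sp, origin = org)
  })

  # TIRM-like precontrast volume on a coarser grid: lesion hyperintense,
  # fat-suppressed-background-like flat elsewhere
  tirm_sp <- c(4, 4, 4)
  tirm_shape <- pmax(as.integer(ceiling(shp * sp / tirm_sp)), 2L)
  t_inside <- .sphere_mask(tirm_shape, tirm_sp, org, ctr_mm, spec$lesion_radius)
  tirm_dat <- array(100, tirm_shape)
  tirm_dat[t_inside] <- 220
  if (spec$noise_sd > 0)
    tirm_dat <- tirm_dat + array(stats::rnorm(prod(tirm_shape), 0,
                                              spec$noise_sd * 100), tirm_shape)
  tirm <- image_volume(tirm_dat, spacing = tirm_sp, origin = org)

  # delayed postcontrast volume on a finer grid, 3 min after the last phase
  pc_sp <- c(1, 1, 1)
  pc_shape <- pmax(as.integer(ceiling(shp * sp / pc_sp)), 2L)
  p_inside <- .sphere_mask(pc_shape, pc_sp, org, ctr_mm, spec$lesion_radius)
  kt_pc <- array(spec$background_ktrans, pc_shape); kt_pc[p_inside] <- spec$true_ktrans
  kep_pc <- array(spec$true_kep, pc_shape)
  t_delay <- times[length(times)] + 180
  times_pc <- c(times, t_delay)
  cp_pc <- generate_aif(spec$aif, times_pc)
  ct_pc <- .ct_matrix(kt_pc, kep_pc, cp_pc, times_pc)[, length(times_pc)]
  pc_sig <- spgr_signal(R1_ms + r1x * ct_pc, spec$M0, spec$TR, spec$dyn_flip_angle)
  if (spec$noise_sd > 0)
    pc_sig <- pc_sig + stats::rnorm(length(pc_sig), 0, 1) *
      (spec$noise_sd * spgr_signal(R1_ms, spec$M0, spec$TR, spec$dyn_flip_angle))
  postc <- image_volume(array(pc_sig, pc_shape), spacing = pc_sp, origin = org)

  idx <- which(inside, arr.ind = TRUE)
  bbox <- rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
  colnames(bbox) <- c("x", "y", "z")

  truth <- list(
    ktrans = image_volume(ktrans, sp, org),
    kep = image_volume(kep, sp, org),
    ve = image_volume(ktrans / kep, sp, org),
    r1 = image_volume(r1_map, sp, org)
  )
  mask <- tumor_mask(image_volume(array(as.numeric(inside), shp), sp, org),
                     threshold = NA_real_, bbox = bbox)

  list(dynamic = dynamic_series(dyn4d, times, sp, org),
       vfa = vfa, flip_angles = spec$flip_angles,
       tirm = tirm, postc = postc,
       truth = truth, mask = mask, bbox = bbox, spec = spec)
}

#' Write a simulated phantom to disk as NIfTI-1 volumes
#'
#' One 4D file (plus times sidecar) for the dynamic series, one 3D file per
#' flip angle, the auxiliary TIRM-like and postcontrast volumes, the truth
#' parameter maps and the truth mask.
#'
#' @param phantom output of [simulate_phantom()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dynamic(phantom$dynamic, file.path(dir, "dynamic.nii.gz"))
  for (i in seq_along(phantom$vfa))
    write_volume(phantom$vfa[[i]],
                 file.path(dir, sprintf("vfa_fa%02d.nii.gz",
                                        as.integer(phantom$flip_angles[i]))))
  write_volume(phantom$tirm, file.path(dir, "tirm.nii.gz"))
  write_volume(phantom$postc, file.path(dir, "postc.nii.gz"))
  for (nm in names(phantom$truth))
    write_volume(phantom$truth[[nm]],
                 file.path(dir, paste0("truth_", nm, ".nii.gz")))
  write_volume(phantom$mask$volume, file.path(dir, "truth_mask.nii.gz"))
  invisible(dir)
}

# tissue concentration for all voxels: group by distinct kep, scale by ktrans
.ct_matrix <- function(ktrans, kep, cp, times) {
  nvox <- length(ktrans)
  uk <- unique(as.vector(kep))
  if (length(uk) <= 64L) {
    g <- conv_exp(cp, times, uk / 60)              # length(uk) x T
    ct <- g[match(as.vector(kep), uk), , drop = FALSE]
  } else {
    ct <- conv_exp(cp, times, as.vector(kep) / 60)
  }
  ct * (as.vector(ktrans) / 60)
}
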