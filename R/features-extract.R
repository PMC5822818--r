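#' Extract the full radiomic feature vector of a lesion
#'
#' Computes 9 shape features from the dynamic-space mask and, for each
#' supplied source image, 13 first-order features (after mu +/- 3 sigma
#' clipping, 256-bin histogram) and 9 GLCM features (after clipping and
#' 32-level quantization, merged 26-neighbour 3D co-occurrence). With the
#' seven canonical images (`r1`, `ktrans`, `kep`, `ve`, `iauc`, `tirm`,
#' `postc`) this yields 9 + 7 x 22 = 163 named features. Each image is
#' evaluated in its native space against a geometry-matched mask.
#'
#' Intensity feature names follow `"<image>__<feature>"` (e.g.
#' `ktrans__energy`, `ktrans__glcm_entropy`); shape features are
#' `"shape__<feature>"`.
#'
#' @param images named list of [image_volume()]s.
#' @param masks a single [tumor_mask()] (used for every image) or a named
#'   list parallel to `images`.
#' @param shape_mask mask used for shape features; defaults to the mask of
#'   the first image.
#' @param n_sigma clip width for [normalize_intensities()].
#' @param n_bins first-order histogram bins; default 256.
#' @param n_levels GLCM grey levels; default 32.
#' @param lesion_id optional lesion identifier attached as attribute.
#' @return Named numeric vector of radiomic features.
#' @export
extract_all <- function(images, masks, shape_mask = NULL, n_sigma = 3,
                        n_bins = 256, n_levels = 32, lesion_id = NULL) {
  if (is.null(names(images)) || any(names(images) == ""))
    stop("extract_all: `images` must be a named list", call. = FALSE)
  if (inherits(masks, "tumor_mask"))
    masks <- stats::setNames(rep(list(masks), length(images)), names(images))
  for (nm in names(images)) {
    if (is.null(masks[[nm]]))
      stop("extract_all: no mask supplied for image `", nm, "`",
           call. = FALSE)
    if (!same_geometry(images[[nm]], masks[[nm]]$volume))
      stop("extract_all: geometry mismatch for image `", nm, "`",
           call. = FALSE)
  }
  if (is.null(shape_mask)) shape_mask <- masks[[1L]]

  out <- shape_features(shape_mask)
  for (nm in names(images)) {
    vals <- normalize_intensities(images[[nm]], masks[[nm]], n_sigma = n_sigma)
    fo <- first_order_features(vals, n_bins = n_bins)
    lev_arr <- array(NA_integer_, dim(images[[nm]]$data))
    midx <- mask_indices(masks[[nm]])
    fin <- is.finite(images[[nm]]$data[midx])
    lev_arr[midx[fin]] <- quantize(vals, n_levels)
    gmask <- masks[[nm]]
    if (!all(fin)) {       # invalid voxels drop out of the texture mask
      mv <- gmask$volume$data
      mv[midx[!fin]] <- 0
      gmask <- tumor_mask(image_volume(mv, gmask$volume$spacing,
                                       gmask$volume$origin),
                          threshold = gmask$threshold, bbox = gmask$bbox)
    }
    gl <- glcm_features(glcm_matrix(lev_arr, gmask, n_levels = n_levels))
    names(fo) <- paste0(nm, "__", names(fo))
    names(gl) <- paste0(nm, "__", names(gl))
    out <- c(out, fo, gl)
  }
  if (anyDuplicated(names(out)))
    stop("extract_all: duplicated feature names", call. = FALSE)
  if (!is.null(lesion_id)) attr(out, "lesion_id") <- lesion_id
  out
}
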