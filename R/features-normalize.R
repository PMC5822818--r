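#' Normalize intensities within a tumour mask
#'
#' Restricts an image to the mask and clips the values to
#' \eqn{[\mu - n\sigma, \mu + n\sigma]}, where \eqn{\mu} and \eqn{\sigma}
#' are the within-mask mean and population standard deviation (divisor N).
#' With \eqn{\sigma = 0} the values are returned unchanged. Missing voxels
#' inside the mask are dropped.
#'
#' @param image an [image_volume()].
#' @param mask a [tumor_mask()] on the same geometry.
#' @param n_sigma clip width in standard deviations; default 3.
#' @return Numeric vector of clipped within-mask values, in mask linear
#'   index order.
#' @export
normalize_intensities <- function(image, mask, n_sigma = 3) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "tumor_mask"))
  stopifnot_same_geometry(image, mask$volume, "image and mask")
  v <- image$data[mask_indices(mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    stop("normalize_intensities: no finite value inside the mask",
         call. = FALSE)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) return(v)
  pmin(pmax(v, mu - n_sigma * sigma), mu + n_sigma * sigma)
}

#' Uniform grey-level quantization
#'
#' Bins values into `n_levels` equal-width levels over their range:
#' level = min(floor((x - min) / w) + 1, n_levels) with
#' w = (max - min)/n_levels. Constant input maps to level 1.
#'
#' @param values numeric vector (non-empty).
#' @param n_levels number of levels (>= 2).
#' @return Integer vector of levels in 1..n_levels.
#' @export
quantize <- function(values, n_levels) {
  if (length(values) == 0L)
    stop("quantize: empty input", call. = FALSE)
  if (n_levels < 2L)
    stop("quantize: need at least 2 levels", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  w <- (hi - lo) / n_levels
  pmin(as.integer(floor((values - lo) / w)) + 1L, as.integer(n_levels))
}
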