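#' Binary tumour mask with provenance
#'
#' @param volume an [image_volume()] with values in \{0, 1\} (NA allowed for
#'   voxels excluded from evaluation).
#' @param threshold relative-enhancement threshold that produced the mask
#'   (NA for truth/external masks).
#' @param bbox bounding box used, or NULL.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(volume, threshold = NA_real_, bbox = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  vals <- volume$data
  if (!all(vals %in% c(0, 1) | is.na(vals)))
    stop("tumor_mask: values must be 0/1", call. = FALSE)
  structure(list(volume = volume, threshold = threshold, bbox = bbox),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat("<tumor_mask> ", sum(x$volume$data == 1, na.rm = TRUE), " voxels of ",
      paste(dim(x$volume$data), collapse = " x "), "\n", sep = "")
  invisible(x)
}

mask_indices <- function(mask) which(mask$volume$data == 1)

#' Relative enhancement map of a dynamic series
#'
#' Per voxel, the maximal signal increase over the post-baseline phases
#' relative to the first time point:
#' \eqn{RE = (\max_{t>t_1} S(t) - S(t_1)) / S(t_1)}. Voxels with
#' non-positive baseline are returned missing. Set `first_post_only = TRUE`
#' to use the first post-baseline phase instead of the maximum.
#'
#' @param series a [dynamic_series()] with at least 2 phases.
#' @param first_post_only logical; see above.
#' @return An [image_volume()] of relative enhancement (dimensionless).
#' @export
relative_enhancement <- function(series, first_post_only = FALSE) {
  stopifnot(inherits(series, "dynamic_series"))
  nt <- dim(series$data)[4L]
  if (nt < 2L)
    stop("relative_enhancement: need at least 2 phases", call. = FALSE)
  ord <- order(series$times)
  shp <- dim(series$data)[1:3]
  S <- matrix(series$data, nrow = prod(shp), ncol = nt)[, ord, drop = FALSE]
  base <- S[, 1L]
  post <- if (first_post_only) S[, 2L] else
    apply(S[, -1L, drop = FALSE], 1L, max)
  re <- (post - base) / base
  re[base <= 0] <- NA_real_
  image_volume(array(re, shp), spacing = series$spacing,
               origin = series$origin)
}

#' Segment a lesion by the 75% enhancement rule
#'
#' Inside a user-supplied bounding box, selects voxels whose relative
#' enhancement strictly exceeds the threshold (default 0.75, i.e. a signal
#' increase higher than 75% of the first time point), then keeps only the
#' largest 26-connected component.
#'
#' @param series a [dynamic_series()].
#' @param bbox 2x3 matrix (rows lo, hi) of voxel index ranges.
#' @param threshold enhancement threshold (fraction); default 0.75.
#' @param first_post_only passed to [relative_enhancement()].
#' @return A [tumor_mask()].
#' @export
segment_lesion <- function(series, bbox, threshold = 0.75,
                           first_post_only = FALSE) {
  stopifnot(inherits(series, "dynamic_series"))
  shp <- dim(series$data)[1:3]
  bbox <- as.matrix(bbox)
  if (any(bbox[1, ] < 1) || any(bbox[2, ] > shp) || any(bbox[1, ] > bbox[2, ]))
    stop("segment_lesion: bbox outside the grid or empty", call. = FALSE)
  re <- relative_enhancement(series, first_post_only = first_post_only)
  sel <- array(FALSE, shp)
  sel[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2], bbox[1, 3]:bbox[2, 3]] <- TRUE
  hit <- sel & !is.na(re$data) & re$data > threshold
  if (!any(hit))
    stop("segment_lesion: no voxel exceeds the enhancement threshold",
         call. = FALSE)
  mask <- tumor_mask(image_volume(array(as.numeric(hit), shp),
                                  series$spacing, series$origin),
                     threshold = threshold, bbox = bbox)
  keep_largest_component(mask)
}

# 26-neighbourhood offsets (13 unique positive directions and their mirrors)
.offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})
.offsets13 <- local({
  g <- .offsets26
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[keep, , drop = FALSE]
})

# edge list between in-mask voxels under 26-connectivity; vertices are
# positions in `lin` (sorted linear indices of mask voxels)
.mask_edges <- function(arr_ind, shp) {
  n <- nrow(arr_ind)
  lin <- arr_ind[, 1] + (arr_ind[, 2] - 1) * shp[1] +
    (arr_ind[, 3] - 1) * shp[1] * shp[2]
  pos <- seq_len(n)
  edges <- vector("list", nrow(.offsets13))
  for (k in seq_len(nrow(.offsets13))) {
    off <- .offsets13[k, ]
    nb <- sweep(arr_ind, 2L, off, `+`)
    okb <- nb[, 1] >= 1 & nb[, 1] <= shp[1] &
      nb[, 2] >= 1 & nb[, 2] <= shp[2] &
      nb[, 3] >= 1 & nb[, 3] <= shp[3]
    nl <- nb[okb, 1] + (nb[okb, 2] - 1) * shp[1] + (nb[okb, 3] - 1) * shp[1] * shp[2]
    m <- match(nl, lin)
    has <- !is.na(m)
    edges[[k]] <- cbind(pos[okb][has], m[has])
  }
  do.call(rbind, edges)
}

#' Keep the largest 26-connected component of a mask
#'
#' Erases voxels disconnected from the biggest connected component. Size
#' ties are broken in favour of the component containing the lowest linear
#' voxel index. Idempotent.
#'
#' @param mask a non-empty [tumor_mask()].
#' @param connectivity only 26 is supported.
#' @return A [tumor_mask()] with exactly one connected component.
#' @export
keep_largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "tumor_mask"))
  if (connectivity != 26)
    stop("keep_largest_component: only 26-connectivity is implemented",
         call. = FALSE)
  shp <- dim(mask$volume$data)
  arr_ind <- which(mask$volume$data == 1, arr.ind = TRUE)
  if (nrow(arr_ind) == 0L)
    stop("keep_largest_component: empty mask", call. = FALSE)
  if (nrow(arr_ind) == 1L) return(mask)
  ed <- .mask_edges(arr_ind, shp)
  g <- igraph::make_empty_graph(n = nrow(arr_ind), directed = FALSE)
  if (!is.null(ed) && nrow(ed) > 0L) g <- igraph::add_edges(g, t(ed))
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie: component whose first-listed voxel (lowest linear index, since
    # which() enumerates in linear order) comes first
    first_seen <- vapply(biggest, function(cid) min(which(comp$membership == cid)),
                         integer(1))
    biggest <- biggest[which.min(first_seen)]
  }
  keep <- comp$membership == biggest
  out <- array(0, shp)
  out[arr_ind[keep, , drop = FALSE]] <- 1
  tumor_mask(image_volume(out, mask$volume$spacing, mask$volume$origin),
             threshold = mask$threshold, bbox = mask$bbox)
}

#' Resample a mask to another grid by nearest neighbour
#'
#' Maps every target voxel centre to physical space and takes the value of
#' the nearest source voxel. Grids must be axis-aligned and overlap in
#' physical space; a resample that yields no lesion voxel is an error.
#'
#' @param mask a [tumor_mask()].
#' @param target_geometry list with `shape` (integer 3), `spacing` (mm) and
#'   `origin` (mm), e.g. `geometry_of`-style or an [image_volume()].
#' @return A [tumor_mask()] on the target grid.
#' @export
resample_mask <- function(mask, target_geometry) {
  stopifnot(inherits(mask, "tumor_mask"))
  tg <- if (inherits(target_geometry, "image_volume"))
    list(shape = dim(target_geometry$data),
         spacing = target_geometry$spacing, origin = target_geometry$origin)
  else target_geometry
  src <- mask$volume
  if (identical(as.integer(tg$shape), as.integer(dim(src$data))) &&
      all(abs(tg$spacing - src$spacing) < 1e-9) &&
      all(abs(tg$origin - src$origin) < 1e-9))
    return(mask)
  sshp <- dim(src$data)
  # nearest source index per target coordinate, per axis
  ax_idx <- lapply(1:3, function(a) {
    coords <- .axis_coords(tg$shape[a], tg$spacing[a], tg$origin[a])
    i <- round((coords - src$origin[a]) / src$spacing[a]) + 1
    i[i < 1 | i > sshp[a]] <- NA_integer_
    as.integer(i)
  })
  if (all(is.na(ax_idx[[1]])) || all(is.na(ax_idx[[2]])) || all(is.na(ax_idx[[3]])))
    stop("resample_mask: grids do not overlap in physical space",
         call. = FALSE)
  out <- array(0, tg$shape)
  gi <- expand.grid(x = ax_idx[[1]], y = ax_idx[[2]], z = ax_idx[[3]])
  inb <- !is.na(gi$x) & !is.na(gi$y) & !is.na(gi$z)
  vals <- numeric(nrow(gi))
  vals[inb] <- src$data[cbind(gi$x[inb], gi$y[inb], gi$z[inb])]
  out[] <- vals
  if (!any(out == 1))
    stop("resample_mask: resampled mask is empty", call. = FALSE)
  tumor_mask(image_volume(out, tg$spacing, tg$origin),
             threshold = mask$threshold, bbox = NULL)
}
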