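#' 3D grey-level co-occurrence matrix
#'
#' One merged, symmetric co-occurrence matrix over the 26-voxel
#' neighbourhood at distance 1: for every in-mask voxel, the grey levels of
#' all 26 neighbouring in-mask voxels are counted (13 unique direction
#' pairs, both orientations), and the counts are normalized to sum 1.
#'
#' @param levels [image_volume()] or integer array of quantized grey levels
#'   (1..n), defined on all mask voxels.
#' @param mask a [tumor_mask()] on the same grid.
#' @param n_levels matrix size; defaults to `max(levels in mask)`.
#' @return A normalized `n_levels x n_levels` matrix summing to 1.
#' @export
glcm_matrix <- function(levels, mask, n_levels = NULL) {
  lv <- if (inherits(levels, "image_volume")) levels$data else as.array(levels)
  stopifnot(inherits(mask, "tumor_mask"))
  if (!identical(dim(lv), dim(mask$volume$data)))
    stop("glcm_matrix: levels/mask shape mismatch", call. = FALSE)
  m <- mask$volume$data == 1
  if (any(!is.finite(lv[m])))
    stop("glcm_matrix: levels undefined on some mask voxels", call. = FALSE)
  if (is.null(n_levels)) n_levels <- max(lv[m])
  shp <- dim(lv)
  idx <- which(m, arr.ind = TRUE)
  counts <- matrix(0, n_levels, n_levels)
  for (k in seq_len(nrow(.offsets13))) {
    off <- .offsets13[k, ]
    nb <- sweep(idx, 2L, off, `+`)
    okb <- nb[, 1] >= 1 & nb[, 1] <= shp[1] &
      nb[, 2] >= 1 & nb[, 2] <= shp[2] &
      nb[, 3] >= 1 & nb[, 3] <= shp[3]
    if (!any(okb)) next
    src <- idx[okb, , drop = FALSE]
    dst <- nb[okb, , drop = FALSE]
    pair_ok <- m[dst]
    if (!any(pair_ok)) next
    li <- lv[src[pair_ok, , drop = FALSE]]
    lj <- lv[dst[pair_ok, , drop = FALSE]]
    tab <- matrix(tabulate(li + (lj - 1L) * n_levels, nbins = n_levels^2),
                  n_levels, n_levels)
    counts <- counts + tab + t(tab)     # symmetrize: both orientations
  }
  total <- sum(counts)
  if (total == 0)
    stop("glcm_matrix: no valid voxel pair (degenerate mask)", call. = FALSE)
  counts / total
}

#' Haralick-type features of a co-occurrence matrix
#'
#' Nine second-order texture statistics of a normalized symmetric GLCM
#' \eqn{P}: energy \eqn{\sum P^2}, contrast \eqn{\sum (i-j)^2 P}, entropy
#' \eqn{-\sum P \log_2 P} (zero cells skipped), homogeneity
#' \eqn{\sum P/(1+|i-j|)}, correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j)P/(\sigma_i\sigma_j)} (defined as 1 when
#' \eqn{\sigma_i\sigma_j = 0}), sum average \eqn{\sum_k k\, p_{x+y}(k)},
#' variance \eqn{\sum (i-\mu)^2 P} with \eqn{\mu} the mean of the marginal
#' means, dissimilarity \eqn{\sum |i-j| P} and autocorrelation
#' \eqn{\sum ij P}.
#'
#' @param P normalized co-occurrence matrix (non-negative, sums to 1).
#' @return Named numeric vector of 9 features, names prefixed `glcm_`.
#' @export
glcm_features <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < 0) || abs(sum(P) - 1) > 1e-8)
    stop("glcm_features: P must be square, non-negative and sum to 1",
         call. = FALSE)
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mui <- sum(seq_len(n) * px); muj <- sum(seq_len(n) * py)
  sdi <- sqrt(sum((seq_len(n) - mui)^2 * px))
  sdj <- sqrt(sum((seq_len(n) - muj)^2 * py))
  corr <- if (sdi * sdj > 0) sum((i - mui) * (j - muj) * P) / (sdi * sdj) else 1
  mu <- (mui + muj) / 2
  # p_{x+y}(k), k = 2..2n
  ks <- 2:(2 * n)
  pxy <- vapply(ks, function(k) sum(P[i + j == k]), numeric(1))
  nz <- P[P > 0]
  c(glcm_energy = sum(P^2),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_entropy = -sum(nz * log2(nz)),
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_correlation = corr,
    glcm_sum_average = sum(ks * pxy),
    glcm_variance = sum((i - mu)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_autocorrelation = sum(i * j * P))
}
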