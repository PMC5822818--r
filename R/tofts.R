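#' Fit the standard Tofts model to a concentration curve
#'
#' Nonlinear least squares over (ktrans, kep) of the Tofts convolution
#' model. Because the model is linear in ktrans at fixed kep, the fit is
#' performed on the profiled objective: for each kep the optimal ktrans has
#' a closed form, and the residual sum of squares is minimized over kep by a
#' global log-grid bracket followed by local refinement. This reaches the
#' global least-squares optimum within the parameter bounds
#' ktrans in [0, 5]/min, kep in [1e-3, 10]/min.
#'
#' @param ct tissue concentration curve (mM) on `times`.
#' @param aif_curve plasma concentration (mM) on `times`.
#' @param times acquisition times (s).
#' @return A list with `ktrans` (1/min), `kep` (1/min), `ve` = ktrans/kep,
#'   `rss` (residual sum of squares) and `converged`.
#' @export
fit_tofts <- function(ct, aif_curve, times) {
  if (length(ct) != length(times) || length(aif_curve) != length(times))
    stop("fit_tofts: curves and times must share one grid", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("fit_tofts: times must be strictly increasing", call. = FALSE)
  fit <- .fit_tofts_matrix(matrix(ct, ncol = 1L), aif_curve, times)
  list(ktrans = fit$ktrans[1L], kep = fit$kep[1L], ve = fit$ve[1L],
       rss = fit$rss[1L], converged = fit$converged[1L])
}

.KEP_LO <- 1e-3; .KEP_HI <- 10; .KTRANS_HI <- 5   # 1/min bounds

# Profiled Tofts least squares, vectorized over voxels.
# ct_mat: T x V concentration matrix. Three stages: coarse log-grid over
# kep, fine local grid shared by voxels with the same coarse argmin, and a
# parabolic interpolation of the RSS in log(kep) at the fine optimum.
.fit_tofts_matrix <- function(ct_mat, aif_curve, times,
                              n_coarse = 48L, n_fine = 17L) {
  nv <- ncol(ct_mat)
  cc <- colSums(ct_mat^2)

  eval_grid <- function(keps) {
    # returns list(num, den): num = G ct (K x V), den = rowSums(G^2)
    G <- conv_exp(aif_curve, times, keps / 60)       # K x T (mM*s units)
    list(num = G %*% ct_mat, den = rowSums(G^2))
  }
  # profiled RSS for a grid: rss[k, v] = cc[v] - kt*(2 num - kt den)
  prof <- function(num, den) {
    kt <- num / den                                  # 1/s scale
    kt <- pmin(pmax(kt, 0), .KTRANS_HI / 60)
    rss <- -kt * (2 * num - kt * den)                # + cc added when needed
    list(kt = kt, rss = rss)
  }

  grid <- exp(seq(log(.KEP_LO), log(.KEP_HI), length.out = n_coarse))
  g1 <- eval_grid(grid)
  p1 <- prof(g1$num, g1$den)
  best <- max.col(-t(p1$rss), ties.method = "first")  # argmin per voxel

  kep_hat <- numeric(nv); kt_hat <- numeric(nv); rss_hat <- numeric(nv)
  for (b in unique(best)) {
    vox <- which(best == b)
    lo <- grid[max(b - 1L, 1L)]; hi <- grid[min(b + 1L, n_coarse)]
    fine <- exp(seq(log(lo), log(hi), length.out = n_fine))
    g2 <- eval_grid(fine)
    p2 <- prof(g2$num[, vox, drop = FALSE], g2$den)
    j <- max.col(-t(p2$rss), ties.method = "first")
    # parabolic refinement in log(kep) on the three points around the minimum
    jj <- pmin(pmax(j, 2L), n_fine - 1L)
    lk <- log(fine)
    f0 <- p2$rss[cbind(jj - 1L, seq_along(vox))]
    f1 <- p2$rss[cbind(jj, seq_along(vox))]
    f2 <- p2$rss[cbind(jj + 1L, seq_along(vox))]
    h <- lk[2L] - lk[1L]
    denom <- f0 - 2 * f1 + f2
    shift <- ifelse(is.finite(denom) & abs(denom) > 0,
                    0.5 * h * (f0 - f2) / denom, 0)
    shift <- pmin(pmax(shift, -h), h)
    kep_v <- exp(lk[jj] + shift)
    kep_v <- pmin(pmax(kep_v, .KEP_LO), .KEP_HI)
    # final profiled ktrans at the refined kep (per-voxel kep values)
    G <- conv_exp(aif_curve, times, kep_v / 60)      # |vox| x T
    num <- rowSums(G * t(ct_mat[, vox, drop = FALSE]))
    den <- rowSums(G^2)
    kt_v <- pmin(pmax(num / den, 0), .KTRANS_HI / 60)
    kep_hat[vox] <- kep_v
    kt_hat[vox] <- kt_v
    rss_hat[vox] <- cc[vox] - kt_v * (2 * num - kt_v * den)
  }

  flat <- cc == 0 | kt_hat <= 0                      # no enhancement
  kt_min <- kt_hat * 60
  kep_min <- kep_hat
  kt_min[flat] <- 0
  kep_min[flat & cc == 0] <- NA_real_
  ve <- ifelse(is.na(kep_min), NA_real_, ifelse(kt_min == 0, 0, kt_min / kep_min))
  list(ktrans = kt_min, kep = kep_min, ve = ve,
       rss = pmax(rss_hat, 0), converged = rep(TRUE, nv))
}
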