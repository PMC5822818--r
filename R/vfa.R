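#' Variable-flip-angle R1/M0 estimation (linearized DESPOT1)
#'
#' Fits the SPGR signal equation across flip angles by the classical
#' linearization: regressing \eqn{S/\sin\alpha} on \eqn{S/\tan\alpha} gives
#' slope \eqn{E_1 = e^{-TR \cdot R_1}} and intercept \eqn{M_0 (1 - E_1)}.
#' Voxels whose fitted slope falls outside (0, 1) are flagged invalid and
#' returned as missing.
#'
#' @param signals numeric vector of signals, one per flip angle.
#' @param flip_angles flip angles (degrees); at least 2 distinct values.
#' @param TR repetition time (ms).
#' @return A list with `R1` (1/ms), `M0` (a.u.) and `valid` (logical).
#' @export
fit_vfa_r1 <- function(signals, flip_angles, TR) {
  if (length(unique(flip_angles)) < 2L)
    stop("fit_vfa_r1: need at least 2 distinct flip angles", call. = FALSE)
  if (length(signals) != length(flip_angles))
    stop("fit_vfa_r1: signals/flip_angles length mismatch", call. = FALSE)
  if (any(signals < 0))
    stop("fit_vfa_r1: signals must be non-negative", call. = FALSE)
  fit <- .vfa_fit_matrix(matrix(signals, nrow = 1L), flip_angles, TR)
  list(R1 = fit$R1[1L], M0 = fit$M0[1L], valid = fit$valid[1L])
}

# vectorized DESPOT1 over a voxels x angles signal matrix
.vfa_fit_matrix <- function(S, flip_angles, TR) {
  a <- flip_angles * pi / 180
  Y <- sweep(S, 2L, sin(a), `/`)
  X <- sweep(S, 2L, tan(a), `/`)
  nA <- length(a)
  xm <- rowMeans(X); ym <- rowMeans(Y)
  sxx <- rowSums(X^2) - nA * xm^2
  sxy <- rowSums(X * Y) - nA * xm * ym
  slope <- sxy / sxx
  valid <- is.finite(slope) & slope > 0 & slope < 1 & sxx > 0
  R1 <- M0 <- rep(NA_real_, nrow(S))
  R1[valid] <- -log(slope[valid]) / TR
  M0[valid] <- (ym[valid] - slope[valid] * xm[valid]) / (1 - slope[valid])
  bad <- valid & (M0 <= 0)
  R1[bad] <- NA_real_; M0[bad] <- NA_real_; valid[bad] <- FALSE
  list(R1 = R1, M0 = M0, valid = valid)
}
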