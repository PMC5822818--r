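#' Convert a dynamic SPGR signal curve to tissue concentration
#'
#' Inverts the SPGR signal equation for \eqn{R_1(t)} at every phase, given
#' the equilibrium signal `M0` and the dynamic flip angle, and maps the
#' relaxation-rate change to concentration through the linear relaxivity
#' relation \eqn{C_t(t) = (R_1(t) - R_1^{base}) / r_1}. The reference rate
#' \eqn{R_1^{base}} is taken from the inversion of the baseline phase(s)
#' themselves, so the baseline concentration is zero by construction;
#' `R1_0` is used as fallback reference when the baseline inversion is
#' invalid. Signals implying \eqn{E_1} outside (0, 1) are clamped into the
#' valid range and flagged.
#'
#' @param series_voxel signal curve (one value per phase).
#' @param R1_0 precontrast relaxation rate (1/ms), e.g. from [fit_vfa_r1()].
#' @param M0 equilibrium signal (a.u.).
#' @param TR repetition time (ms).
#' @param flip_angle dynamic flip angle (degrees).
#' @param r1_relaxivity contrast relaxivity (1/mM/s).
#' @param baseline_phases indices of precontrast phases; default 1.
#' @return A list with `ct` (mM, per phase) and `clamped` (logical per
#'   phase, `TRUE` where the inversion was out of range).
#' @export
signal_to_concentration <- function(series_voxel, R1_0, M0, TR, flip_angle,
                                    r1_relaxivity = 4.5,
                                    baseline_phases = 1L) {
  out <- .concentration_matrix(matrix(series_voxel, nrow = 1L),
                               R1_0, M0, TR, flip_angle, r1_relaxivity,
                               baseline_phases)
  list(ct = drop(out$ct), clamped = drop(out$clamped))
}

# vectorized over a voxels x phases signal matrix; R1_0, M0 per voxel
.concentration_matrix <- function(S, R1_0, M0, TR, flip_angle,
                                  r1_relaxivity, baseline_phases = 1L) {
  a <- flip_angle * pi / 180
  Ms <- M0 * sin(a)
  num <- Ms - S                      # voxels x phases (Ms recycled by column)
  den <- Ms - S * cos(a)
  E1 <- num / den
  clamped <- !is.finite(E1) | E1 <= 0 | E1 >= 1
  eps <- 1e-12
  E1[!is.finite(E1)] <- eps        # S at/above saturation: R1 pinned high
  E1 <- pmin(pmax(E1, eps), 1 - eps)
  R1_t <- -log(E1) / TR              # 1/ms
  base <- if (length(baseline_phases) > 1L)
    rowMeans(R1_t[, baseline_phases, drop = FALSE])
  else R1_t[, baseline_phases]
  bad_base <- !is.finite(base)
  base[bad_base] <- R1_0[bad_base]
  ct <- (R1_t - base) / (r1_relaxivity / 1000)   # relaxivity in 1/mM/ms
  ct[, baseline_phases] <- 0
  list(ct = ct, clamped = clamped)
}
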