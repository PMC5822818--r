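#' Spoiled gradient-echo steady-state signal
#'
#' Signal of an RF-spoiled gradient echo (VIBE-type) acquisition,
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},\qquad
#'       E_1 = e^{-TR \cdot R_1}.}
#'
#' @param R1 longitudinal relaxation rate (1/ms); must be > 0. Vectorized.
#' @param M0 equilibrium signal (arbitrary units).
#' @param TR repetition time (ms).
#' @param flip_angle flip angle (degrees), in (0, 90).
#' @return Signal in the units of `M0`.
#' @export
spgr_signal <- function(R1, M0, TR, flip_angle) {
  if (any(R1 <= 0, na.rm = TRUE))
    stop("spgr_signal: R1 must be positive", call. = FALSE)
  if (flip_angle <= 0 || flip_angle >= 90)
    stop("spgr_signal: flip_angle must be in (0, 90) degrees", call. = FALSE)
  a <- flip_angle * pi / 180
  E1 <- exp(-TR * R1)
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

# Exact convolution of a piecewise-linear input with an exponential kernel.
#
# Computes I(t_n) = integral_0^{t_n} cp(tau) exp(-k (t_n - tau)) dtau on the
# sample grid, assuming cp linear between samples and zero before times[1].
# Recursion over segments is exact for piecewise-linear cp:
#   I_n = E I_{n-1} + cp_{n-1} (q - r) + cp_n r
# with E = exp(-k d), q = (1-E)/k, r = (d - q)/(k d), d = t_n - t_{n-1}.
# `k` may be a vector: returns a length(k) x length(times) matrix.
# Units: k in 1/s, times in s, result in mM*s (for cp in mM).
conv_exp <- function(cp, times, k) {
  nt <- length(times)
  nk <- length(k)
  out <- matrix(0, nrow = nk, ncol = nt)
  if (nt < 2L) return(out)
  acc <- numeric(nk)
  for (n in 2:nt) {
    d <- times[n] - times[n - 1L]
    kd <- k * d
    E <- exp(-kd)
    q <- ifelse(kd > 1e-8, (1 - E) / k, d * (1 - kd / 2 + kd^2 / 6))
    r <- ifelse(kd > 1e-8, (d - q) / (k * d), d / 2 * (1 - kd / 3 + kd^2 / 12))
    acc <- E * acc + cp[n - 1L] * (q - r) + cp[n] * r
    out[, n] <- acc
  }
  out
}

#' Tofts-model tissue concentration
#'
#' Forward standard Tofts model
#' \deqn{C_t(t) = k^{trans} \int_0^t C_p(\tau) e^{-k_{ep}(t-\tau)} d\tau}
#' evaluated exactly on the time grid under a piecewise-linear plasma curve.
#'
#' @param ktrans transfer constant (1/min); must be >= 0.
#' @param kep efflux rate constant (1/min); must be > 0.
#' @param aif_curve plasma concentration (mM) sampled on `times`.
#' @param times acquisition times (s), strictly increasing.
#' @return Tissue concentration (mM) on the time grid; starts at 0.
#' @export
simulate_tissue_concentration <- function(ktrans, kep, aif_curve, times) {
  if (length(ktrans) != 1L || ktrans < 0)
    stop("simulate_tissue_concentration: ktrans must be a single value >= 0",
         call. = FALSE)
  if (length(kep) != 1L || kep <= 0)
    stop("simulate_tissue_concentration: kep must be a single positive value",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("simulate_tissue_concentration: times must be strictly increasing",
         call. = FALSE)
  if (length(aif_curve) != length(times))
    stop("simulate_tissue_concentration: curve/times length mismatch",
         call. = FALSE)
  drop((ktrans / 60) * conv_exp(aif_curve, times, kep / 60))
}
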