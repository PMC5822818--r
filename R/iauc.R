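#' Initial area under the concentration curve
#'
#' Trapezoidal integral of tissue concentration from contrast onset over a
#' fixed early window (default 60 s), with linear interpolation of the curve
#' at the window edges. If the window extends past the last phase the
#' integral is truncated there and flagged.
#'
#' @param ct tissue concentration (mM) on `times`.
#' @param times acquisition times (s).
#' @param window_s integration window length (s); must be > 0.
#' @param onset contrast arrival time (s); default the second phase time
#'   (injection at the end of the first phase).
#' @return A list with `iauc` (mM s) and `truncated` (logical).
#' @export
compute_iauc <- function(ct, times, window_s = 60, onset = times[2L]) {
  if (window_s <= 0) stop("compute_iauc: window_s must be > 0", call. = FALSE)
  if (length(ct) != length(times))
    stop("compute_iauc: ct/times length mismatch", call. = FALSE)
  t_end <- onset + window_s
  truncated <- t_end > times[length(times)]
  if (truncated) t_end <- times[length(times)]
  if (onset >= t_end) return(list(iauc = 0, truncated = truncated))
  # sample points: onset, grid points strictly inside, window end
  inner <- times[times > onset & times < t_end]
  tt <- c(onset, inner, t_end)
  vv <- stats::approx(times, ct, xout = tt, rule = 2)$y
  iauc <- sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
  list(iauc = iauc, truncated = truncated)
}
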