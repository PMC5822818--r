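#' First-order intensity features
#'
#' Thirteen histogram and moment statistics of the (clipped) within-mask
#' values: energy \eqn{\sum x_i^2}, entropy and uniformity from the
#' `n_bins`-bin intensity histogram (probabilities \eqn{p_k}; entropy
#' \eqn{-\sum p \log_2 p} skipping empty bins, uniformity \eqn{\sum p^2}),
#' kurtosis (standardized fourth central moment, not excess-corrected),
#' maximum, mean, mean absolute deviation, median, minimum, root mean
#' square, skewness, standard deviation and variance (population, divisor
#' N). At zero variance skewness and kurtosis are defined as 0 and the
#' single-bin histogram gives entropy 0, uniformity 1.
#'
#' @param values numeric vector of at least 1 value (already normalized /
#'   clipped upstream).
#' @param n_bins histogram bin count; default 256. Binning is equal-width
#'   over `[min, max]`, left-closed with a right-closed final bin.
#' @return Named numeric vector of 13 features.
#' @export
first_order_features <- function(values, n_bins = 256) {
  if (length(values) == 0L)
    stop("first_order_features: empty input", call. = FALSE)
  x <- as.numeric(values)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdev <- sqrt(m2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0

  p <- .hist_probs(x, n_bins)
  p <- p[p > 0]

  c(energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    kurtosis = kurt,
    max = max(x),
    mean = mu,
    mad = mean(abs(x - mu)),
    median = stats::median(x),
    min = min(x),
    rms = sqrt(sum(x^2) / n),
    skewness = skew,
    std = sdev,
    uniformity = sum(p^2),
    variance = m2)
}

# equal-width histogram probabilities over [min, max]; constant input puts
# all mass in bin 1
.hist_probs <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    p <- numeric(n_bins); p[1L] <- 1
    return(p)
  }
  w <- (hi - lo) / n_bins
  bin <- pmin(as.integer(floor((x - lo) / w)) + 1L, as.integer(n_bins))
  tabulate(bin, nbins = n_bins) / length(x)
}
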