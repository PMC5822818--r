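#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). When either
#' vector has zero rank variance the correlation is defined as 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("spearman_corr: need equal lengths >= 3", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(0)
  stats::cor(rx, ry)
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with ties
#' counting 1/2 (the Mann-Whitney relation): computed from mid-ranks as
#' \eqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_0 n_1)}.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("auc: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Mann-Whitney U test
#'
#' U from rank sums with mid-rank tie handling. The two-sided p-value is
#' exact by complete enumeration of group assignments when
#' \eqn{n_0 n_1 \le 64} and there are no ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param group0,group1 numeric vectors, both non-empty.
#' @return A list with `U` (statistic for `group0`), `p` (two-sided) and
#'   `exact` (logical).
#' @export
mann_whitney_u <- function(group0, group1) {
  n0 <- length(group0); n1 <- length(group1)
  if (n0 == 0L || n1 == 0L)
    stop("mann_whitney_u: both groups must be non-empty", call. = FALSE)
  xall <- c(group0, group1)
  r <- rank(xall)
  U <- sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2    # U for group0
  ties <- any(duplicated(xall))
  if (!ties && n0 * n1 <= 64) {
    # exact: enumerate all assignments of ranks to group0
    combos <- utils::combn(n0 + n1, n0)
    Us <- colSums(matrix(r[combos], nrow = n0)) - n0 * (n0 + 1) / 2
    pl <- mean(Us <= U); pu <- mean(Us >= U)
    p <- min(1, 2 * min(pl, pu))
    return(list(U = U, p = p, exact = TRUE))
  }
  n <- n0 + n1
  tie_counts <- table(xall)
  mu <- n0 * n1 / 2
  sigma2 <- n0 * n1 / 12 * ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Bonferroni significance flags
#'
#' @param pvals numeric vector of p-values.
#' @param alpha family-wise level; default 0.05.
#' @param m number of comparisons; defaults to `length(pvals)`.
#' @return Logical vector: `pvals < alpha / m`.
#' @export
bonferroni_flags <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (m < 1L) stop("bonferroni_flags: m must be >= 1", call. = FALSE)
  pvals < alpha / m
}
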