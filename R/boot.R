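#' Imbalance-adjusted bootstrap sample
#'
#' Draws n indices with replacement where every draw first picks a class
#' with probability 1/2 and then a member uniformly within that class, so
#' the expected class balance of the sample is 1:1 regardless of the
#' original imbalance. The out-of-bag set is the indices never drawn.
#'
#' @param labels binary labels (0/1 or logical); both classes present.
#' @param size sample size; defaults to `length(labels)`.
#' @return Integer vector of indices (a multiset of size `size`).
#' @export
iabr_sample <- function(labels, size = length(labels)) {
  y <- as.integer(as.logical(labels))
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  if (length(i0) == 0L || length(i1) == 0L)
    stop("iabr_sample: both classes must be present", call. = FALSE)
  cls <- stats::runif(size) < 0.5
  idx <- integer(size)
  n1 <- sum(cls)
  if (n1 > 0L) idx[cls] <- i1[sample.int(length(i1), n1, replace = TRUE)]
  if (n1 < size) idx[!cls] <- i0[sample.int(length(i0), size - n1, replace = TRUE)]
  idx
}

# Logistic regression via maximum likelihood with a tiny ridge fallback on
# separation / non-convergence. X: matrix without intercept column.
# Returns list(coef = c(intercept, betas), ridge = logical).
.logistic_fit <- function(X, y, ridge = 1e-6) {
  Xi <- cbind(1, X)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial())),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$converged && all(is.finite(fit$coefficients)) &&
    all(abs(fit$coefficients) < 1e3)
  if (ok) return(list(coef = fit$coefficients, ridge = FALSE))
  list(coef = .logistic_irls_ridge(Xi, y, ridge), ridge = TRUE)
}

# penalized IRLS (ridge on all coefficients incl. intercept kept unpenalized)
.logistic_irls_ridge <- function(Xi, y, lambda, maxit = 100L) {
  p <- ncol(Xi)
  beta <- numeric(p)
  pen <- diag(lambda, p); pen[1L, 1L] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xi * w)
    beta_new <- tryCatch(solve(XtW %*% Xi + pen, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

.zscore_stats <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

.zscore_apply <- function(X, st) sweep(sweep(X, 2L, st$mu), 2L, st$sd, `/`)

#' 0.632+ bootstrap AUC of a logistic model
#'
#' Estimates the out-of-sample AUC of an unpenalized logistic regression on
#' a feature subset by the 0.632+ rule: per imbalance-adjusted bootstrap
#' sample, the model is fitted in-bag (features z-scored by in-bag
#' statistics) and scored out-of-bag; the apparent AUC (fit and score on the
#' full data) and the mean out-of-bag AUC are combined as
#' \deqn{\widehat{AUC} = (1-w)\,AUC_{app} + w\,AUC_{oob},\quad
#'       w = \frac{0.632}{1 - 0.368 R}}
#' with the relative overfitting rate
#' \eqn{R = (AUC_{app} - AUC_{oob}) / (AUC_{app} - 0.5)} clamped to [0, 1]
#' (0.5 being the no-information AUC). Sensitivity, specificity and
#' accuracy are evaluated out-of-bag at the probability-0.5 operating
#' point. Samples whose out-of-bag set is single-class are redrawn (up to
#' 25 retries) and skipped thereafter.
#'
#' @param feature_subset character vector of column names of `table`.
#' @param table lesions x features matrix/data.frame.
#' @param outcome binary labels.
#' @param n_boot bootstrap samples; default 1000.
#' @param seed integer seed.
#' @return A list of class `performance_estimate`: `auc`, `auc_se`,
#'   `auc_apparent`, `auc_oob`, `sensitivity`, `specificity`, `accuracy`
#'   (each `*_se` alongside), `n_boot_used`, `n_skipped`.
#' @export
bootstrap_632plus_auc <- function(feature_subset, table, outcome,
                                  n_boot = 1000, seed = 1L) {
  if (length(feature_subset) == 0L)
    stop("bootstrap_632plus_auc: empty feature subset", call. = FALSE)
  X <- as.matrix(table)[, feature_subset, drop = FALSE]
  y <- as.integer(as.logical(outcome))
  if (length(unique(y)) < 2L)
    stop("bootstrap_632plus_auc: outcome has a single class", call. = FALSE)

  st_full <- .zscore_stats(X)
  Z <- .zscore_apply(X, st_full)
  fit_full <- .logistic_fit(Z, y)
  score_full <- drop(cbind(1, Z) %*% fit_full$coef)
  auc_app <- auc(score_full, y)

  set.seed(seed)
  aucs <- sens <- spec <- accs <- numeric(0)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- NULL
    for (try in seq_len(25L)) {
      cand <- iabr_sample(y)
      oob <- setdiff(seq_along(y), cand)
      if (length(oob) >= 2L && length(unique(y[oob])) == 2L &&
          length(unique(y[cand])) == 2L) { idx <- cand; break }
    }
    if (is.null(idx)) { skipped <- skipped + 1L; next }
    st <- .zscore_stats(X[idx, , drop = FALSE])
    Zb <- .zscore_apply(X[idx, , drop = FALSE], st)
    fit <- .logistic_fit(Zb, y[idx])
    Zo <- .zscore_apply(X[oob, , drop = FALSE], st)
    sc <- drop(cbind(1, Zo) %*% fit$coef)
    yo <- y[oob]
    aucs <- c(aucs, auc(sc, yo))
    pred <- as.integer(stats::plogis(sc) > 0.5)
    sens <- c(sens, if (any(yo == 1L)) mean(pred[yo == 1L] == 1L) else NA_real_)
    spec <- c(spec, if (any(yo == 0L)) mean(pred[yo == 0L] == 0L) else NA_real_)
    accs <- c(accs, mean(pred == yo))
  }
  if (length(aucs) == 0L)
    stop("bootstrap_632plus_auc: no usable bootstrap sample", call. = FALSE)

  auc_oob <- mean(aucs)
  gam <- 0.5
  R <- if (auc_app > auc_oob && auc_app > gam)
    (auc_app - auc_oob) / (auc_app - gam) else 0
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  est <- (1 - w) * auc_app + w * auc_oob

  B <- length(aucs)
  se <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  structure(list(auc = est, auc_se = se(aucs),
                 auc_apparent = auc_app, auc_oob = auc_oob,
                 overfit_rate = R, weight = w,
                 sensitivity = mean(sens, na.rm = TRUE), sensitivity_se = se(sens),
                 specificity = mean(spec, na.rm = TRUE), specificity_se = se(spec),
                 accuracy = mean(accs, na.rm = TRUE), accuracy_se = se(accs),
                 n_boot_used = B, n_skipped = skipped),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("<performance_estimate> AUC %.3f +/- %.3f (apparent %.3f, oob %.3f)\n",
              x$auc, x$auc_se, x$auc_apparent, x$auc_oob))
  invisible(x)
}
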