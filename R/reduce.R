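#' Gain of a candidate feature
#'
#' Linear combination of outcome association and redundancy used by the
#' stepwise reduction:
#' \deqn{gain = \delta |\rho(candidate, outcome)| -
#'       (1-\delta)\,\overline{MIC}(candidate, selected)}
#' where \eqn{\rho} is the Spearman correlation and the second term is the
#' mean MIC against the already-selected features. With nothing selected the
#' gain is \eqn{|\rho|}.
#'
#' @param candidate numeric feature vector.
#' @param outcome binary outcome labels.
#' @param selected list of already-selected feature vectors (may be empty).
#' @param delta association weight in [0, 1]; default 0.5.
#' @param rho optional precomputed |Spearman| (e.g. a bootstrap-averaged
#'   estimate); when `NULL` the plain correlation is used.
#' @return The gain value.
#' @export
gain <- function(candidate, outcome, selected = list(), delta = 0.5,
                 rho = NULL) {
  if (is.null(rho)) rho <- abs(spearman_corr(candidate, as.numeric(outcome)))
  if (length(selected) == 0L) return(rho)
  red <- mean(vapply(selected, function(s) mic(candidate, s), numeric(1)))
  delta * rho - (1 - delta) * red
}

#' Stepwise feature-set reduction by the gain equation
#'
#' Selects up to `k` features by forward search: the first feature maximizes
#' the absolute Spearman correlation with the outcome; each following
#' feature maximizes [gain()], trading association against MIC redundancy
#' with the features already chosen. Spearman terms are estimated as means
#' over `n_boot` imbalance-adjusted bootstrap samples ([iabr_sample()]);
#' set `n_boot = 0` for plain correlations. MIC values are computed once
#' per feature pair and cached. Gain ties are broken by column order.
#'
#' @param table numeric matrix or data.frame, lesions x features, with
#'   column names.
#' @param outcome binary labels (both classes present).
#' @param k reduced-set size; default 25.
#' @param n_boot bootstrap samples for the Spearman estimate; default 1000.
#' @param delta gain weight; default 0.5.
#' @param seed integer seed for the bootstrap draws.
#' @param outcome_name label stored in the result.
#' @return A list of class `reduced_set`: `features` (ordered names),
#'   `gains`, `rho` (association estimates), `outcome_name`.
#' @export
reduce_features <- function(table, outcome, k = 25, n_boot = 1000,
                            delta = 0.5, seed = 1L,
                            outcome_name = "outcome") {
  X <- as.matrix(table)
  if (is.null(colnames(X)))
    stop("reduce_features: `table` needs column names", call. = FALSE)
  y <- as.integer(as.logical(outcome))
  if (length(unique(y)) < 2L)
    stop("reduce_features: outcome has a single class", call. = FALSE)
  if (nrow(X) != length(y))
    stop("reduce_features: table/outcome size mismatch", call. = FALSE)
  p <- ncol(X)
  k <- min(k, p)

  rho <- .iabr_spearman(X, y, n_boot, seed)

  sel <- integer(0)
  gains <- numeric(0)
  mic_cache <- matrix(NA_real_, p, p)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    if (length(sel) == 0L) {
      g <- rho
    } else {
      g <- rep(NA_real_, p)
      for (j in remaining) {
        miss <- sel[is.na(mic_cache[j, sel])]
        for (s in miss) {
          v <- mic(X[, j], X[, s])
          mic_cache[j, s] <- mic_cache[s, j] <- v
        }
        g[j] <- delta * rho[j] - (1 - delta) * mean(mic_cache[j, sel])
      }
    }
    g[sel] <- NA_real_
    pick <- which.max(g)             # first maximum: ties -> column order
    sel <- c(sel, pick)
    gains <- c(gains, g[pick])
    remaining <- setdiff(remaining, pick)
  }
  structure(list(features = colnames(X)[sel], gains = gains,
                 rho = rho[sel], outcome_name = outcome_name,
                 delta = delta, n_boot = n_boot),
            class = "reduced_set")
}

# |Spearman| per feature, averaged over IABR samples (plain when n_boot = 0)
.iabr_spearman <- function(X, y, n_boot, seed) {
  p <- ncol(X)
  plain <- vapply(seq_len(p), function(j)
    abs(spearman_corr(X[, j], as.numeric(y))), numeric(1))
  if (n_boot <= 0) return(plain)
  set.seed(seed)
  acc <- numeric(p)
  used <- 0L
  for (b in seq_len(n_boot)) {
    idx <- iabr_sample(y)
    yb <- y[idx]
    if (length(unique(yb)) < 2L) next
    Xb <- X[idx, , drop = FALSE]
    ryb <- rank(yb)
    if (stats::var(ryb) == 0) next
    rb <- apply(Xb, 2L, rank)
    ok <- apply(rb, 2L, stats::var) > 0
    r <- rep(0, p)
    r[ok] <- abs(suppressWarnings(stats::cor(rb[, ok, drop = FALSE], ryb)))
    acc <- acc + r
    used <- used + 1L
  }
  if (used == 0L) return(plain)
  acc / used
}

#' @export
print.reduced_set <- function(x, ...) {
  cat("<reduced_set> ", length(x$features), " features for outcome `",
      x$outcome_name, "`\n", sep = "")
  invisible(x)
}
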