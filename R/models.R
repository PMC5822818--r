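#' Stepwise logistic models of increasing order
#'
#' Builds multivariable logistic models of order 1..`max_order` from a
#' reduced feature set by forward selection on the 0.632+ bootstrap AUC:
#' the order-1 model is the single best feature, and order i adds to the
#' order-(i-1) model the feature that maximizes the order-i model's
#' estimated AUC ([bootstrap_632plus_auc()]). AUC ties are broken by the
#' candidate's rank in the reduced set. Within an order, every candidate is
#' evaluated on the same bootstrap draws (a per-order seed), so comparisons
#' are paired.
#'
#' @param reduced a `reduced_set` from [reduce_features()] (or a character
#'   vector of feature names).
#' @param table lesions x features matrix/data.frame.
#' @param outcome binary labels.
#' @param max_order largest model order; default 10.
#' @param n_boot bootstrap samples per evaluation; default 1000.
#' @param seed integer seed.
#' @return A list of class `model_curve`: `orders`, `auc` (best 0.632+ AUC
#'   per order), `features` (list: selected subset per order),
#'   `performance` (list of `performance_estimate` per order).
#' @export
build_models <- function(reduced, table, outcome, max_order = 10,
                         n_boot = 1000, seed = 1L) {
  feats <- if (inherits(reduced, "reduced_set")) reduced$features
  else as.character(reduced)
  if (length(feats) == 0L)
    stop("build_models: empty reduced set", call. = FALSE)
  max_order <- min(max_order, length(feats))

  current <- character(0)
  orders <- seq_len(max_order)
  curve_auc <- numeric(max_order)
  sel_feats <- vector("list", max_order)
  perf <- vector("list", max_order)
  for (ord in orders) {
    cand <- setdiff(feats, current)
    order_seed <- .derive_seed(seed, ord)
    best_i <- NA_integer_; best_auc <- -Inf; best_perf <- NULL
    for (i in seq_along(cand)) {
      pe <- bootstrap_632plus_auc(c(current, cand[i]), table, outcome,
                                  n_boot = n_boot, seed = order_seed)
      if (pe$auc > best_auc + 1e-12) {   # ties keep earlier reduced-set rank
        best_auc <- pe$auc; best_i <- i; best_perf <- pe
      }
    }
    current <- c(current, cand[best_i])
    curve_auc[ord] <- best_auc
    sel_feats[[ord]] <- current
    perf[[ord]] <- best_perf
  }
  structure(list(orders = orders, auc = curve_auc, features = sel_feats,
                 performance = perf, n_boot = n_boot, seed = seed),
            class = "model_curve")
}

#' @export
print.model_curve <- function(x, ...) {
  cat("<model_curve> best 0.632+ AUC by order:\n")
  print(stats::setNames(round(x$auc, 3), x$orders))
  invisible(x)
}

#' Final logistic model at the AUC-optimal order
#'
#' Picks the order maximizing the AUC-versus-order curve (ties resolved
#' toward the smaller order), then computes the final coefficients as the
#' mean over imbalance-adjusted bootstrap in-bag logistic fits of that
#' feature combination. Features are z-scored by full-data statistics
#' before fitting; the returned model stores both the standardized
#' coefficients with the transform and their raw-scale equivalents, so it
#' applies as \eqn{g(x) = \sum \beta x + \beta_0},
#' \eqn{p = 1/(1+e^{-g})}.
#'
#' @param curve a `model_curve` from [build_models()].
#' @param table,outcome training data.
#' @param n_boot bootstrap samples for coefficient averaging; default 1000.
#' @param seed integer seed.
#' @param outcome_name label stored in the model.
#' @return A list of class `logistic_model`: `outcome`, `order`,
#'   `features`, `coefficients` (raw scale), `intercept`,
#'   `coefficients_std`, `intercept_std`, `transform` (mu/sd),
#'   `performance` (a `performance_estimate`).
#' @export
select_final_model <- function(curve, table, outcome, n_boot = 1000,
                               seed = 1L, outcome_name = "outcome") {
  stopifnot(inherits(curve, "model_curve"))
  ord <- which.max(curve$auc)           # first maximum: smaller order wins
  feats <- curve$features[[ord]]
  X <- as.matrix(table)[, feats, drop = FALSE]
  y <- as.integer(as.logical(outcome))
  st <- .zscore_stats(X)
  Z <- .zscore_apply(X, st)

  set.seed(.derive_seed(seed, 101L))
  coefs <- matrix(NA_real_, n_boot, length(feats) + 1L)
  used <- 0L
  for (b in seq_len(n_boot)) {
    idx <- NULL
    for (try in seq_len(25L)) {
      cand <- iabr_sample(y)
      if (length(unique(y[cand])) == 2L) { idx <- cand; break }
    }
    if (is.null(idx)) next
    used <- used + 1L
    coefs[used, ] <- .logistic_fit(Z[idx, , drop = FALSE], y[idx])$coef
  }
  if (used == 0L)
    stop("select_final_model: no usable bootstrap sample", call. = FALSE)
  cf <- colMeans(coefs[seq_len(used), , drop = FALSE])
  beta_std <- cf[-1L]; b0_std <- cf[1L]
  beta_raw <- beta_std / st$sd
  b0_raw <- b0_std - sum(beta_std * st$mu / st$sd)

  perf <- bootstrap_632plus_auc(feats, table, outcome, n_boot = n_boot,
                                seed = .derive_seed(seed, 202L))
  structure(list(outcome = outcome_name, order = length(feats),
                 features = feats,
                 coefficients = stats::setNames(beta_raw, feats),
                 intercept = unname(b0_raw),
                 coefficients_std = stats::setNames(beta_std, feats),
                 intercept_std = unname(b0_std),
                 transform = st, performance = perf,
                 n_boot = used),
            class = "logistic_model")
}

#' Apply a logistic model to feature values
#'
#' Evaluates \eqn{g(x) = \sum \beta x + \beta_0} and
#' \eqn{p = 1/(1 + e^{-g})} on raw (untransformed) feature values, i.e. in
#' the printed-coefficient format.
#'
#' @param model a `logistic_model`, or any list with `features`,
#'   `coefficients`, `intercept`.
#' @param newdata named vector, or matrix/data.frame with the model's
#'   feature columns.
#' @return A list with `g` (linear predictor) and `p` (probability).
#' @export
apply_model <- function(model, newdata) {
  if (is.null(dim(newdata))) {
    nm <- names(newdata)
    if (is.null(nm)) {
      if (length(newdata) != length(model$features))
        stop("apply_model: unnamed input must match the model order",
             call. = FALSE)
      nm <- model$features
    }
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, nm))
  }
  X <- as.matrix(newdata)[, model$features, drop = FALSE]
  g <- drop(X %*% model$coefficients) + model$intercept
  list(g = g, p = stats::plogis(g))
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> outcome `", x$outcome, "`, order ", x$order,
      ", 0.632+ AUC ", round(x$performance$auc, 3), "\n", sep = "")
  invisible(x)
}

#' Univariate Mann-Whitney analysis of a reduced feature set
#'
#' Tests every feature of the reduced set against the outcome with the
#' Mann-Whitney U test and flags Bonferroni-significant features at level
#' `alpha` corrected by the reduced-set size.
#'
#' @param reduced a `reduced_set` or character vector of feature names.
#' @param table,outcome data.
#' @param alpha family-wise level; default 0.05.
#' @return data.frame with columns `feature`, `U`, `p`, `significant`.
#' @export
univariate_analysis <- function(reduced, table, outcome, alpha = 0.05) {
  feats <- if (inherits(reduced, "reduced_set")) reduced$features
  else as.character(reduced)
  y <- as.integer(as.logical(outcome))
  X <- as.matrix(table)
  res <- lapply(feats, function(f)
    mann_whitney_u(X[y == 0L, f], X[y == 1L, f]))
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(feature = feats,
             U = vapply(res, `[[`, numeric(1), "U"),
             p = p,
             significant = bonferroni_flags(p, alpha = alpha, m = length(feats)),
             stringsAsFactors = FALSE)
}

# deterministic sub-seed derivation (kept inside 32-bit integer range)
.derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(tag) * 1299721) %% 2147483647)
}
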