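test_that("gain reduces to |Spearman| with nothing selected and penalizes redundancy", {
  set.seed(1)
  x <- rnorm(40); y <- rep(0:1, 20)
  g0 <- gain(x, y, list())
  expect_equal(g0, abs(spearman_corr(x, as.numeric(y))))
  # candidate identical to a selected feature: MIC term is 1
  g1 <- gain(x, y, list(x), delta = 0.5)
  expect_equal(g1, 0.5 * g0 - 0.5 * 1, tolerance = 1e-12)
  expect_lt(g1, g0)
})

test_that("gain on a toy table matches composed component oracles", {
  set.seed(2)
  n <- 20
  f1 <- rnorm(n); f2 <- f1 + rnorm(n, 0, 0.4); y <- as.numeric(f1 > 0)
  rho <- abs(spearman_corr(f2, y))
  red <- mic(f2, f1)              # exact path at n = 20
  expect_equal(gain(f2, y, list(f1), delta = 0.5),
               0.5 * rho - 0.5 * red, tolerance = 1e-12)
})

test_that("feature reduction returns k ordered unique features", {
  X <- random_table(30, 40)
  y <- rep(0:1, 15)
  red <- reduce_features(X, y, k = 10, n_boot = 20, seed = 1)
  expect_length(red$features, 10)
  expect_false(anyDuplicated(red$features) > 0)
  # exhaustion: k above the feature count ranks everything
  red2 <- reduce_features(X[, 1:6], y, k = 25, n_boot = 10, seed = 1)
  expect_length(red2$features, 6)
  expect_error(reduce_features(X, rep(1, 30), k = 5), "single class")
})

test_that("a feature determining the outcome is selected first", {
  hits <- 0L
  for (s in 1:10) {
    X <- random_table(40, 30, seed = s)
    set.seed(1000 + s)
    y <- rep(0:1, each = 20)
    X[, 17] <- y + rnorm(40, 0, 0.15)
    red <- reduce_features(X, y, k = 5, n_boot = 50, seed = s)
    hits <- hits + (red$features[1] == colnames(X)[17])
  }
  expect_gte(hits, 9)
})

test_that("IABR samples are class-balanced in expectation", {
  set.seed(3)
  y <- rep(c(0, 1), c(45, 5))
  frac <- replicate(1000, mean(y[iabr_sample(y)]))
  expect_lt(abs(mean(frac) - 0.5), 0.03)
  # balanced labels reduce to uniform marginal draw probabilities
  y2 <- rep(0:1, each = 25)
  idx <- replicate(500, iabr_sample(y2))
  counts <- tabulate(idx, nbins = 50)
  expect_lt(max(abs(counts / sum(counts) - 1 / 50)), 0.005)
  expect_error(iabr_sample(rep(1, 10)), "classes")
})

test_that("0.632+ estimate is the common value at its fixed point", {
  # perfectly separated single feature: apparent = oob = 1 -> estimate 1
  set.seed(4)
  y <- rep(0:1, each = 15)
  X <- cbind(f = y * 10 + rnorm(30, 0, 0.01))
  pe <- bootstrap_632plus_auc("f", X, y, n_boot = 40, seed = 1)
  expect_equal(pe$auc_apparent, 1)
  expect_equal(pe$auc_oob, 1)
  expect_equal(pe$auc, 1)
  expect_equal(pe$sensitivity, 1)
  expect_equal(pe$specificity, 1)
})

test_that("0.632+ estimate is bounded by out-of-bag and apparent AUC", {
  set.seed(5)
  for (s in 1:5) {
    y <- rep(0:1, each = 20)
    X <- cbind(a = y * 0.8 + rnorm(40), b = rnorm(40))
    pe <- bootstrap_632plus_auc(c("a", "b"), X, y, n_boot = 40, seed = s)
    expect_gte(pe$auc + 1e-12, min(pe$auc_apparent, pe$auc_oob))
    expect_lte(pe$auc - 1e-12, max(pe$auc_apparent, pe$auc_oob))
    expect_gte(pe$weight, 0.632); expect_lte(pe$weight, 1)
  }
})

test_that("0.632+ estimate tracks the generative AUC on a planted cohort", {
  # single feature ~ N(0,1) vs N(mu,1): generative AUC = pnorm(mu/sqrt(2))
  set.seed(6)
  mu <- 1.8
  y <- rep(0:1, each = 25)
  X <- cbind(f = rnorm(50) + mu * y)
  pe <- bootstrap_632plus_auc("f", X, y, n_boot = 200, seed = 2)
  gen_auc <- pnorm(mu / sqrt(2))
  expect_lt(abs(pe$auc - gen_auc), 0.08)
})

test_that("model building returns one point per order and respects the base case", {
  X <- random_table(30, 8)
  y <- rep(0:1, 15)
  X[, 2] <- X[, 2] + 1.2 * y
  cur <- build_models(colnames(X), X, y, max_order = 1, n_boot = 25, seed = 1)
  expect_length(cur$auc, 1)
  expect_length(cur$features[[1]], 1)
  cur10 <- build_models(colnames(X)[1:5], X, y, max_order = 10,
                        n_boot = 25, seed = 1)
  expect_length(cur10$auc, 5)   # capped by the reduced-set size
})

test_that("final model selection takes the AUC argmax with smaller-order ties", {
  curve <- structure(list(orders = 1:3, auc = c(0.7, 0.9, 0.9),
                          features = list("a", c("a", "b"), c("a", "b", "c")),
                          performance = vector("list", 3)),
                     class = "model_curve")
  set.seed(7)
  y <- rep(0:1, each = 15)
  X <- cbind(a = y + rnorm(30, 0, 0.5), b = rnorm(30), c = rnorm(30))
  fm <- select_final_model(curve, X, y, n_boot = 30, seed = 1)
  expect_equal(fm$order, 2)
  expect_equal(fm$features, c("a", "b"))
  expect_length(fm$coefficients, 2)
})

test_that("the printed ki67-style model applies as g = sum(beta x) + b0", {
  model <- list(features = c("ktrans__energy", "kep__median"),
                coefficients = c(ktrans__energy = 1, kep__median = 0.03),
                intercept = -1.78)
  out <- apply_model(model, c(ktrans__energy = 1.78, kep__median = 0))
  expect_equal(out$g, 0)
  expect_equal(out$p, 0.5)
})

test_that("reduction is permutation-equivariant in feature order", {
  X <- random_table(30, 12)
  y <- rep(0:1, 15)
  X[, 4] <- X[, 4] + y
  red <- reduce_features(X, y, k = 6, n_boot = 0, seed = 1)
  perm <- c(7:12, 1:6)
  red_p <- reduce_features(X[, perm], y, k = 6, n_boot = 0, seed = 1)
  expect_setequal(red$features, red_p$features)
})

test_that("full runs are reproducible under a fixed seed", {
  X <- random_table(24, 10)
  y <- rep(0:1, 12)
  X[, 3] <- X[, 3] + y
  r1 <- reduce_features(X, y, k = 5, n_boot = 25, seed = 5)
  r2 <- reduce_features(X, y, k = 5, n_boot = 25, seed = 5)
  expect_identical(r1, r2)
  c1 <- build_models(r1, X, y, max_order = 3, n_boot = 25, seed = 5)
  c2 <- build_models(r2, X, y, max_order = 3, n_boot = 25, seed = 5)
  expect_identical(c1$auc, c2$auc)
  m1 <- select_final_model(c1, X, y, n_boot = 25, seed = 5)
  m2 <- select_final_model(c2, X, y, n_boot = 25, seed = 5)
  expect_identical(m1$coefficients, m2$coefficients)
})

test_that("univariate analysis flags strong features under Bonferroni", {
  set.seed(8)
  y <- rep(0:1, each = 20)
  X <- cbind(strong = y * 3 + rnorm(40, 0, 0.5),
             weak = rnorm(40))
  uni <- univariate_analysis(c("strong", "weak"), X, y)
  expect_true(uni$significant[uni$feature == "strong"])
  expect_false(uni$significant[uni$feature == "weak"])
  expect_equal(nrow(uni), 2)
})
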