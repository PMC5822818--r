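test_that("VFA fit recovers R1 and M0 from noiseless SPGR signals", {
  fa <- c(2, 5, 8, 12, 15, 20)
  s <- vapply(fa, function(a) spgr_signal(0.001, 1000, 5.3, a), numeric(1))
  fit <- fit_vfa_r1(s, fa, 5.3)
  expect_true(fit$valid)
  expect_equal(fit$R1, 0.001, tolerance = 1e-6)
  expect_equal(fit$M0, 1000, tolerance = 1e-6)

  # scale equivariance: doubling M0 doubles fitted M0, leaves R1 unchanged
  fit2 <- fit_vfa_r1(2 * s, fa, 5.3)
  expect_equal(fit2$R1, fit$R1, tolerance = 1e-9)
  expect_equal(fit2$M0, 2 * fit$M0, tolerance = 1e-6)
})

test_that("degenerate VFA inputs are flagged or rejected", {
  expect_false(fit_vfa_r1(rep(0, 6), c(2, 5, 8, 12, 15, 20), 5.3)$valid)
  expect_error(fit_vfa_r1(c(1, 2), c(5, 5), 5.3), "distinct")
})

test_that("a flat series converts to zero concentration", {
  base <- spgr_signal(0.001, 1000, 5.3, 20)
  out <- signal_to_concentration(rep(base, 60), 0.001, 1000, 5.3, 20)
  expect_equal(out$ct, rep(0, 60))
})

test_that("signal-to-concentration inverts the forward simulation", {
  t <- default_times()
  cp <- generate_aif(aif_model(onset_time = 9), t)
  ct_true <- simulate_tissue_concentration(0.25, 0.5, cp, t)
  R1t <- 0.001 + (4.5 / 1000) * ct_true
  S <- spgr_signal(R1t, 1000, 5.3, 20)
  out <- signal_to_concentration(S, 0.001, 1000, 5.3, 20)
  expect_equal(out$ct, ct_true, tolerance = 0.005)
  expect_false(any(out$clamped))

  # doubling the relaxivity halves the concentration exactly
  out2 <- signal_to_concentration(S, 0.001, 1000, 5.3, 20, r1_relaxivity = 9)
  expect_equal(out2$ct, out$ct / 2, tolerance = 1e-12)
})

test_that("Tofts fit recovers noiseless parameters within 1%", {
  t <- default_times()
  cp <- generate_aif(aif_model(onset_time = 9), t)
  ct <- simulate_tissue_concentration(0.2, 0.5, cp, t)
  fit <- fit_tofts(ct, cp, t)
  expect_equal(fit$ktrans, 0.2, tolerance = 0.01)
  expect_equal(fit$kep, 0.5, tolerance = 0.01)
  expect_equal(fit$ve, fit$ktrans / fit$kep, tolerance = 1e-12)
})

test_that("zero concentration fits to zero transfer", {
  t <- default_times()
  cp <- generate_aif(aif_model(onset_time = 9), t)
  fit <- fit_tofts(rep(0, length(t)), cp, t)
  expect_equal(fit$ktrans, 0)
})

test_that("iAUC matches hand-computed integrals", {
  # constant 1 mM over a 60 s window
  t <- seq(0, 120, by = 10)
  expect_equal(compute_iauc(rep(1, length(t)), t, 60, onset = 0)$iauc, 60)
  expect_equal(compute_iauc(rep(0, length(t)), t, 60, onset = 0)$iauc, 0)
  # rising 0 -> 1 mM over 0..30 s then flat: 15 + 30 = 45 mM s
  ct <- ifelse(t <= 30, t / 30, 1)
  expect_equal(compute_iauc(ct, t, 60, onset = 0)$iauc, 45)
  # window past the last phase: truncated and flagged
  out <- compute_iauc(rep(1, 4), c(0, 10, 20, 30), 60, onset = 0)
  expect_true(out$truncated)
  expect_equal(out$iauc, 30)
})

test_that("iAUC is monotone under pointwise-larger curves", {
  t <- default_times()
  set.seed(5)
  for (i in 1:10) {
    a <- cumsum(runif(length(t)))
    b <- a + runif(length(t))
    expect_lte(compute_iauc(a, t)$iauc, compute_iauc(b, t)$iauc)
  }
})

test_that("map fitting recovers truth on a noiseless phantom ROI", {
  spec <- small_phantom_spec()
  ph <- simulate_phantom(spec)
  maps <- compute_pk_maps(ph$dynamic, ph$vfa, ph$flip_angles, spec$aif,
                          roi = ph$bbox)
  les <- which(ph$mask$volume$data == 1)
  expect_lt(abs(median(maps$ktrans$data[les]) - spec$true_ktrans) /
              spec$true_ktrans, 0.02)
  expect_lt(abs(median(maps$kep$data[les]) - spec$true_kep) /
              spec$true_kep, 0.02)
  expect_lt(abs(median(maps$r1$data[les]) - spec$true_R1) / spec$true_R1,
            0.02)
  # ve consistency where defined
  ok <- is.finite(maps$ve$data) & is.finite(maps$kep$data) &
    maps$ve$data < 1
  expect_equal(maps$ve$data[ok] * maps$kep$data[ok], maps$ktrans$data[ok],
               tolerance = 1e-9)
})

test_that("maps are restricted to the ROI and respect phase permutations", {
  spec <- small_phantom_spec()
  ph <- simulate_phantom(spec)
  ctr <- as.integer(spec$lesion_center)
  roi1 <- rbind(ctr, ctr)
  maps <- compute_pk_maps(ph$dynamic, ph$vfa, ph$flip_angles, spec$aif,
                          roi = roi1)
  expect_equal(sum(is.finite(maps$ktrans$data)), 1)

  # permuting phases together with their times changes nothing
  set.seed(9)
  perm <- sample(seq_along(spec$times))
  dyn_p <- dynamic_series(ph$dynamic$data[, , , perm, drop = FALSE],
                          spec$times[perm],
                          ph$dynamic$spacing, ph$dynamic$origin)
  maps_p <- compute_pk_maps(dyn_p, ph$vfa, ph$flip_angles, spec$aif,
                            roi = roi1)
  expect_equal(maps_p$ktrans$data, maps$ktrans$data)
})

test_that("geometry mismatches between series and VFA volumes are rejected", {
  ph <- simulate_phantom(small_phantom_spec())
  bad <- ph$vfa
  bad[[1]] <- image_volume(bad[[1]]$data, spacing = c(1, 1, 1))
  expect_error(compute_pk_maps(ph$dynamic, bad, ph$flip_angles,
                               ph$spec$aif),
               "geometry")
})
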