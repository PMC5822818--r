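test_that("mu +/- 3 sigma clipping matches direct computation", {
  vals <- c(rep(0, 99), 1000)
  arr <- array(0, c(100, 1, 1)); arr[] <- vals
  img <- image_volume(arr)
  m <- mask_from_array(array(1, c(100, 1, 1)))
  mu <- mean(vals); sig <- sqrt(mean((vals - mu)^2))
  out <- normalize_intensities(img, m)
  expect_equal(max(out), mu + 3 * sig)
  expect_equal(sum(out == mu + 3 * sig), 1)
  # constant image: sigma = 0 no-op
  img2 <- image_volume(array(7, c(4, 4, 4)))
  m2 <- mask_from_array(array(1, c(4, 4, 4)))
  expect_equal(normalize_intensities(img2, m2), rep(7, 64))
  # values already inside the band are untouched (uniform draws stay
  # within one sd of the mean times 3)
  arr3 <- array(runif(64), c(4, 4, 4))
  img3 <- image_volume(arr3)
  expect_equal(sort(normalize_intensities(img3, m2)), sort(as.numeric(arr3)))
})

test_that("quantization follows the left-closed equal-width rule", {
  expect_equal(quantize(c(0, 1), 2), c(1L, 2L))
  expect_equal(quantize(rep(3.7, 5), 8), rep(1L, 5))
  expect_equal(quantize(c(0, 0.5, 1), 4), c(1L, 3L, 4L))
  expect_error(quantize(numeric(0), 4), "empty")
  expect_error(quantize(1:3, 1), "2 levels")
})

test_that("shape features match hand-computed voxel geometry", {
  one <- array(0, c(3, 3, 3)); one[2, 2, 2] <- 1
  f <- shape_features(mask_from_array(one))
  expect_equal(unname(f["shape__n_voxels"]), 1)
  expect_equal(unname(f["shape__volume"]), 1)
  expect_equal(unname(f["shape__surface_area"]), 6)
  expect_equal(unname(f["shape__max_diameter"]), 0)
  expect_equal(unname(f["shape__sphericity"]), (pi / 6)^(1 / 3),
               tolerance = 1e-12)

  two <- array(0, c(4, 3, 3)); two[2:3, 2, 2] <- 1
  f2 <- shape_features(mask_from_array(two))
  expect_equal(unname(f2["shape__n_voxels"]), 2)
  expect_equal(unname(f2["shape__volume"]), 2)
  expect_equal(unname(f2["shape__surface_area"]), 10)
  expect_equal(unname(f2["shape__max_diameter"]), 1)
})

test_that("sphericity is the reciprocal of spherical disproportion", {
  ph <- simulate_phantom(small_phantom_spec())
  f <- shape_features(ph$mask)
  expect_equal(unname(f["shape__sphericity"]),
               1 / unname(f["shape__spherical_disproportion"]),
               tolerance = 1e-12)
})

test_that("digitized-sphere sphericity sits at the staircase-surface limit", {
  # face counting measures the staircase surface, which for a sphere
  # converges to 1.5x the smooth area; sphericity therefore concentrates at
  # 2/3 rather than 1, and never exceeds 1
  sph <- vapply(c(4, 6, 9, 12), function(r) {
    spec <- phantom_spec(grid_shape = rep(2 * ceiling(r / 2) + 5, 3),
                         spacing = c(2, 2, 2), lesion_radius = r,
                         noise_sd = 0)
    ctr_mm <- (spec$lesion_center - 1) * spec$spacing
    arr <- dceradiomics:::.sphere_mask(spec$grid_shape, spec$spacing,
                                       c(0, 0, 0), ctr_mm, r)
    unname(shape_features(mask_from_array(arr, spacing = spec$spacing))["shape__sphericity"])
  }, numeric(1))
  expect_true(all(abs(sph - 2 / 3) < 0.07))
  expect_true(all(sph <= 1.05))
})

test_that("first-order features match hand arithmetic", {
  f <- first_order_features(c(1, 2, 2))
  expect_equal(unname(f["energy"]), 9)
  expect_equal(unname(f["mean"]), 5 / 3)
  expect_equal(unname(f["median"]), 2)
  expect_equal(unname(f["rms"]), sqrt(3))

  fc <- first_order_features(rep(4, 10))
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["uniformity"]), 1)
  expect_equal(unname(fc["variance"]), 0)
  expect_equal(unname(fc["skewness"]), 0)
  expect_equal(unname(fc["kurtosis"]), 0)

  # 1..8: eight occupied bins of the 256-bin histogram, uniform
  f8 <- first_order_features(1:8)
  expect_equal(unname(f8["entropy"]), 3)
  expect_equal(unname(f8["uniformity"]), 1 / 8)
})

test_that("first-order features equal definitional formulas on random vectors", {
  set.seed(1)
  for (i in 1:50) {
    x <- rnorm(sample(5:200, 1))
    f <- first_order_features(x)
    n <- length(x); mu <- mean(x); m2 <- mean((x - mu)^2)
    expect_equal(unname(f["energy"]), sum(x^2), tolerance = 1e-12)
    expect_equal(unname(f["variance"]), m2, tolerance = 1e-12)
    expect_equal(unname(f["std"]), sqrt(m2), tolerance = 1e-12)
    expect_equal(unname(f["mad"]), mean(abs(x - mu)), tolerance = 1e-12)
    expect_equal(unname(f["skewness"]), mean((x - mu)^3) / m2^1.5,
                 tolerance = 1e-12)
    expect_equal(unname(f["kurtosis"]), mean((x - mu)^4) / m2^2,
                 tolerance = 1e-12)
    expect_equal(unname(f["rms"]), sqrt(mean(x^2)), tolerance = 1e-12)
  }
})

test_that("GLCM counts equal a brute-force triple-loop pair counter", {
  set.seed(2)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (rep in 1:50) {
    shp <- sample(3:6, 3, replace = TRUE)
    lv <- array(sample(1:4, prod(shp), replace = TRUE), shp)
    msk <- array(runif(prod(shp)) < 0.7, shp)
    if (sum(msk) < 2) next
    # brute force: every voxel, every 26-neighbour, both in mask
    counts <- matrix(0, 4, 4)
    for (x in 1:shp[1]) for (y in 1:shp[2]) for (z in 1:shp[3]) {
      if (!msk[x, y, z]) next
      for (o in seq_len(nrow(offs))) {
        nx <- x + offs$dx[o]; ny <- y + offs$dy[o]; nz <- z + offs$dz[o]
        if (nx < 1 || nx > shp[1] || ny < 1 || ny > shp[2] ||
            nz < 1 || nz > shp[3]) next
        if (!msk[nx, ny, nz]) next
        counts[lv[x, y, z], lv[nx, ny, nz]] <-
          counts[lv[x, y, z], lv[nx, ny, nz]] + 1
      }
    }
    if (sum(counts) == 0) {
      expect_error(glcm_matrix(lv, mask_from_array(msk), n_levels = 4),
                   "degenerate")
      next
    }
    P <- glcm_matrix(lv, mask_from_array(msk), n_levels = 4)
    expect_equal(P, counts / sum(counts), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("GLCM edge cases behave as defined", {
  lv <- array(1L, c(2, 2, 2))
  P <- glcm_matrix(lv, mask_from_array(array(1, c(2, 2, 2))), n_levels = 3)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  lv2 <- array(c(1L, 2L), c(2, 1, 1))
  P2 <- glcm_matrix(lv2, mask_from_array(array(1, c(2, 1, 1))), n_levels = 2)
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)

  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  expect_error(glcm_matrix(array(1L, c(3, 3, 3)), mask_from_array(single)),
               "degenerate")
})

test_that("GLCM features match point-mass and uniform hand evaluations", {
  # all mass at (k, k)
  P <- matrix(0, 5, 5); P[3, 3] <- 1
  f <- glcm_features(P)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_homogeneity"]), 1)
  expect_equal(unname(f["glcm_dissimilarity"]), 0)
  expect_equal(unname(f["glcm_autocorrelation"]), 9)
  expect_equal(unname(f["glcm_sum_average"]), 6)
  expect_equal(unname(f["glcm_correlation"]), 1)  # degenerate convention

  # uniform 2x2
  U <- matrix(0.25, 2, 2)
  fu <- glcm_features(U)
  expect_equal(unname(fu["glcm_energy"]), 0.25)
  expect_equal(unname(fu["glcm_entropy"]), 2)
  expect_equal(unname(fu["glcm_contrast"]), 0.5)
  expect_equal(unname(fu["glcm_correlation"]), 0)
})

test_that("GLCM features equal a definitional summation oracle", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    M <- matrix(runif(n * n), n)
    M <- (M + t(M)); M <- M / sum(M)
    f <- glcm_features(M)
    # independent summation over all cells
    e <- ctr <- ent <- hom <- sa <- va <- dis <- ac <- 0
    px <- rowSums(M); py <- colSums(M)
    mui <- sum((1:n) * px); muj <- sum((1:n) * py)
    mu <- (mui + muj) / 2
    for (a in 1:n) for (b in 1:n) {
      p <- M[a, b]
      e <- e + p^2; ctr <- ctr + (a - b)^2 * p
      if (p > 0) ent <- ent - p * log2(p)
      hom <- hom + p / (1 + abs(a - b))
      va <- va + (a - mu)^2 * p
      dis <- dis + abs(a - b) * p
      ac <- ac + a * b * p
      sa <- sa + (a + b) * p
    }
    expect_equal(unname(f["glcm_energy"]), e, tolerance = 1e-12)
    expect_equal(unname(f["glcm_contrast"]), ctr, tolerance = 1e-12)
    expect_equal(unname(f["glcm_entropy"]), ent, tolerance = 1e-12)
    expect_equal(unname(f["glcm_homogeneity"]), hom, tolerance = 1e-12)
    expect_equal(unname(f["glcm_sum_average"]), sa, tolerance = 1e-12)
    expect_equal(unname(f["glcm_variance"]), va, tolerance = 1e-12)
    expect_equal(unname(f["glcm_dissimilarity"]), dis, tolerance = 1e-12)
    expect_equal(unname(f["glcm_autocorrelation"]), ac, tolerance = 1e-12)
  }
})

test_that("the full extraction yields 163 uniquely named features", {
  ph <- simulate_phantom(small_phantom_spec(noise_sd = 0.02, seed = 7L))
  fv <- lesion_features(ph)
  expect_length(fv, 163)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_equal(sum(startsWith(names(fv), "shape__")), 9)
  for (img in c("r1", "ktrans", "kep", "ve", "iauc", "tirm", "postc"))
    expect_equal(sum(startsWith(names(fv), paste0(img, "__"))), 22)
  expect_true(all(is.finite(fv)))
})

test_that("dropping an image drops exactly its 22 features", {
  ph <- simulate_phantom(small_phantom_spec(noise_sd = 0.02, seed = 8L))
  m <- ph$mask
  imgs <- list(a = ph$truth$ktrans, b = ph$truth$kep)
  f2 <- extract_all(list(a = image_volume(array(rnorm(prod(dim(m$volume$data))),
                                                dim(m$volume$data)),
                                          m$volume$spacing)),
                    m)
  expect_length(f2, 9 + 22)
})

test_that("intensity shifts move location features but not texture", {
  set.seed(4)
  shp <- c(8, 8, 8)
  arr <- array(rnorm(prod(shp)), shp)
  m <- mask_from_array(array(as.numeric(runif(prod(shp)) < 0.6), shp))
  i1 <- image_volume(arr)
  i2 <- image_volume(arr + 100)
  f1 <- extract_all(list(x = i1), m)
  f2 <- extract_all(list(x = i2), m)
  for (nm in c("x__entropy", "x__uniformity", "x__variance", "x__skewness",
               grep("glcm", names(f1), value = TRUE)))
    expect_equal(unname(f2[nm]), unname(f1[nm]), tolerance = 1e-9)
  expect_equal(unname(f2["x__mean"]), unname(f1["x__mean"]) + 100,
               tolerance = 1e-9)
  expect_equal(unname(f2["x__median"]), unname(f1["x__median"]) + 100,
               tolerance = 1e-9)
})

test_that("axis-aligned rotations leave all features unchanged", {
  ph <- simulate_phantom(small_phantom_spec(noise_sd = 0.02, seed = 9L))
  shp <- c(8, 8, 8)
  set.seed(10)
  arr <- array(rnorm(prod(shp)), shp)
  msk <- array(0, shp); msk[3:6, 2:7, 3:5] <- 1
  rot_xy <- function(a) aperm(a, c(2, 1, 3))[shp[2]:1, , , drop = FALSE]
  f1 <- extract_all(list(x = image_volume(arr)), mask_from_array(msk))
  f2 <- extract_all(list(x = image_volume(rot_xy(arr))),
                    mask_from_array(rot_xy(msk)))
  expect_equal(f2, f1, tolerance = 1e-10)
})
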