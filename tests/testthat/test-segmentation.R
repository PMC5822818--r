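make_series <- function(curves, times = c(0, 9, 18)) {
  # curves: list of per-voxel signal curves laid on a small grid
  n <- length(curves)
  arr <- array(100, dim = c(n, 1, 1, length(times)))
  for (i in seq_len(n)) arr[i, 1, 1, ] <- curves[[i]]
  dynamic_series(arr, times)
}

test_that("relative enhancement follows its definition", {
  s <- make_series(list(c(100, 180, 150),  # RE = 0.8
                        c(100, 100, 100),  # RE = 0
                        c(0, 50, 80)))     # zero baseline -> missing
  re <- relative_enhancement(s)
  expect_equal(re$data[1, 1, 1], 0.8)
  expect_equal(re$data[2, 1, 1], 0)
  expect_true(is.na(re$data[3, 1, 1]))
  expect_error(relative_enhancement(
    dynamic_series(array(1, c(2, 2, 2, 1)), 0)), "2 phases")
})

test_that("segmentation applies a strict threshold", {
  s <- make_series(list(c(100, 180, 120),    # RE 0.8 -> in
                        c(100, 170, 160)))   # RE 0.7 -> out
  m <- segment_lesion(s, rbind(c(1, 1, 1), c(2, 1, 1)), threshold = 0.75)
  expect_equal(as.numeric(m$volume$data), c(1, 0))
  # exactly at the threshold is excluded
  s2 <- make_series(list(c(100, 175, 120), c(100, 180, 100)))
  m2 <- segment_lesion(s2, rbind(c(1, 1, 1), c(2, 1, 1)), threshold = 0.75)
  expect_equal(as.numeric(m2$volume$data), c(0, 1))
  # nothing above threshold -> error
  expect_error(segment_lesion(s2, rbind(c(1, 1, 1), c(2, 1, 1)),
                              threshold = 2), "threshold")
})

test_that("noiseless phantom segmentation equals the truth mask", {
  ph <- simulate_phantom(small_phantom_spec())
  m <- segment_lesion(ph$dynamic, rbind(c(1, 1, 1), dim(ph$dynamic$data)[1:3]))
  expect_identical(m$volume$data, ph$mask$volume$data)
})

test_that("raising the threshold never grows the voxel set", {
  ph <- simulate_phantom(small_phantom_spec(noise_sd = 0.05, seed = 11L))
  re <- relative_enhancement(ph$dynamic)
  thresholds <- c(0, 0.25, 0.5, 0.75, 1)
  counts <- vapply(thresholds,
                   function(th) sum(re$data > th, na.rm = TRUE), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("largest-component cleanup keeps the biggest blob and is idempotent", {
  arr <- array(0, c(10, 10, 3))
  arr[1:5, 1:2, 1] <- 1            # 10 voxels
  arr[8:10, 9, 3] <- 1             # 3 voxels, disconnected
  m <- mask_from_array(arr)
  out <- keep_largest_component(m)
  expect_equal(sum(out$volume$data), 10)
  expect_equal(out$volume$data[1, 1, 1], 1)
  out2 <- keep_largest_component(out)
  expect_identical(out2$volume$data, out$volume$data)
})

test_that("diagonally touching voxels are one 26-connected component", {
  arr <- array(0, c(4, 4, 4))
  arr[2, 2, 2] <- 1
  arr[3, 3, 3] <- 1                # corner neighbour
  out <- keep_largest_component(mask_from_array(arr))
  expect_equal(sum(out$volume$data), 2)
  expect_error(keep_largest_component(mask_from_array(array(0, c(2, 2, 2)))),
               "empty")
})

test_that("identity resampling returns the mask unchanged", {
  ph <- simulate_phantom(small_phantom_spec())
  tg <- list(shape = dim(ph$mask$volume$data),
             spacing = ph$mask$volume$spacing,
             origin = ph$mask$volume$origin)
  expect_identical(resample_mask(ph$mask, tg)$volume$data,
                   ph$mask$volume$data)
})

test_that("2x upsampling of one voxel yields its 8 sub-voxels", {
  arr <- array(0, c(4, 4, 4))
  arr[2, 2, 2] <- 1
  m <- mask_from_array(arr, spacing = c(2, 2, 2))
  # halved spacing, origin shifted so sub-voxel centres tile the coarse voxel
  tg <- list(shape = c(8, 8, 8), spacing = c(1, 1, 1),
             origin = c(-0.5, -0.5, -0.5))
  out <- resample_mask(m, tg)
  expect_equal(sum(out$volume$data), 8)
})

test_that("down-then-up resampling preserves sphere volume approximately", {
  ph <- simulate_phantom(small_phantom_spec())
  coarse <- list(shape = c(7, 7, 7), spacing = c(4, 4, 4), origin = c(0, 0, 0))
  fine <- list(shape = dim(ph$mask$volume$data),
               spacing = ph$mask$volume$spacing,
               origin = ph$mask$volume$origin)
  down <- resample_mask(ph$mask, coarse)
  up <- resample_mask(down, fine)
  v0 <- sum(ph$mask$volume$data) * prod(fine$spacing)
  v1 <- sum(up$volume$data) * prod(fine$spacing)
  expect_lt(abs(v1 - v0), prod(coarse$spacing) * 8)
  # disjoint grids are an error
  far <- list(shape = c(4, 4, 4), spacing = c(1, 1, 1),
              origin = c(1000, 1000, 1000))
  expect_error(resample_mask(ph$mask, far), "overlap|empty")
})
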