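# Small phantoms shared by the test suite. Grids are kept small so the
# forward simulation and voxelwise fits stay fast; the physics is identical
# to the default acquisition (60 phases at 9 s, TR 5.3 ms, FAs 2..20 deg).

small_phantom_spec <- function(noise_sd = 0, seed = 1L, ...) {
  phantom_spec(grid_shape = c(14, 14, 14), spacing = c(2, 2, 2),
               lesion_radius = 7, noise_sd = noise_sd, seed = seed, ...)
}

small_cohort_spec <- function(n_lesions = 12, effect = 1.6, noise_sd = 0.02,
                              seed = 1L, tasks = "ki67") {
  cohort_spec(n_lesions = n_lesions, class_balance = 0.5, tasks = tasks,
              effect_map = stats::setNames(list(c(ktrans = effect)), tasks),
              lesion_sd = 0.15,
              template = small_phantom_spec(noise_sd = noise_sd),
              seed = seed)
}

default_times <- function() seq(0, by = 9, length.out = 60)

# mask helper: build a tumor_mask from a logical/0-1 array
mask_from_array <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  tumor_mask(image_volume(array(as.numeric(arr), dim(arr)), spacing, origin))
}

# random feature table with named columns
random_table <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%03d", 1:p)))
}
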