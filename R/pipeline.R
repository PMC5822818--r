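#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end run with the package
#' defaults: cohort generation, enhancement-threshold segmentation,
#' pharmacokinetic mapping, 163-feature extraction, gain-equation reduction
#' and 0.632+ bootstrap model building. The returned list round-trips
#' through YAML unchanged and every stochastic stage derives its seed from
#' the single master `seed`.
#'
#' @param n_lesions cohort size.
#' @param tasks outcome names.
#' @param effect_map per-task planted multiplicative effects (see
#'   [cohort_spec()]).
#' @param class_balance fraction positive per task.
#' @param noise_sd phantom noise level (fraction of baseline signal).
#' @param lesion_sd between-lesion log-normal variability.
#' @param threshold segmentation enhancement threshold.
#' @param iauc_window iAUC window (s).
#' @param k reduced-set size.
#' @param delta gain weight.
#' @param max_order largest model order.
#' @param n_boot bootstrap samples (reduction and modeling).
#' @param template_args named list of [phantom_spec()] overrides (grid
#'   shape, lesion radius, ...) applied to the cohort template.
#' @param seed master seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_lesions = 40, tasks = c("ki67", "grade"),
                            effect_map = list(ki67 = c(ktrans = 1.6),
                                              grade = c(kep = 1.5)),
                            class_balance = 0.5, noise_sd = 0.02,
                            lesion_sd = 0.15, threshold = 0.75,
                            iauc_window = 60, k = 25, delta = 0.5,
                            max_order = 10, n_boot = 1000,
                            template_args = list(), seed = 1L) {
  structure(list(n_lesions = n_lesions, tasks = tasks,
                 effect_map = effect_map, class_balance = class_balance,
                 noise_sd = noise_sd, lesion_sd = lesion_sd,
                 threshold = threshold, iauc_window = iauc_window,
                 k = k, delta = delta, max_order = max_order,
                 n_boot = n_boot, template_args = template_args,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' Named effect vectors are converted to maps so their names survive the
#' round trip.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$effect_map <- lapply(obj$effect_map, as.list)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to the [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("read_config: no such file: ", paste(path, collapse = ""),
         call. = FALSE)
  usr <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(usr)) {
    val <- usr[[nm]]
    if (nm == "effect_map") val <- lapply(val, unlist)
    cfg[[nm]] <- val
  }
  cfg
}

#' Extract the full feature vector of one simulated lesion
#'
#' The per-lesion analysis chain: 75%-enhancement segmentation inside the
#' lesion bounding box, pharmacokinetic mapping restricted to that box,
#' nearest-neighbour resampling of the tumour mask to the TIRM and
#' postcontrast grids, and extraction of the 163 radiomic features from
#' the five maps plus the two auxiliary images.
#'
#' @param phantom one element of `generate_cohort()$phantoms`.
#' @param threshold segmentation threshold.
#' @param iauc_window iAUC window (s).
#' @param pad voxels of padding around the truth bounding box used for both
#'   the segmentation search region and the fitting ROI.
#' @return Named numeric feature vector (163 entries).
#' @export
lesion_features <- function(phantom, threshold = 0.75, iauc_window = 60,
                            pad = 2L) {
  shp <- dim(phantom$dynamic$data)[1:3]
  bbox <- phantom$bbox
  roi <- rbind(lo = pmax(bbox[1, ] - pad, 1L),
               hi = pmin(bbox[2, ] + pad, shp))
  mask <- segment_lesion(phantom$dynamic, roi, threshold = threshold)
  maps <- compute_pk_maps(phantom$dynamic, phantom$vfa, phantom$flip_angles,
                          aif = phantom$spec$aif, roi = roi,
                          TR = phantom$spec$TR,
                          dyn_flip_angle = phantom$spec$dyn_flip_angle,
                          r1_relaxivity = phantom$spec$r1_relaxivity,
                          iauc_window = iauc_window)
  mask_tirm <- resample_mask(mask, phantom$tirm)
  mask_postc <- resample_mask(mask, phantom$postc)
  images <- list(r1 = maps$r1, ktrans = maps$ktrans, kep = maps$kep,
                 ve = maps$ve, iauc = maps$iauc,
                 tirm = phantom$tirm, postc = phantom$postc)
  masks <- list(r1 = mask, ktrans = mask, kep = mask, ve = mask,
                iauc = mask, tirm = mask_tirm, postc = mask_postc)
  extract_all(images, masks, shape_mask = mask)
}

#' Run the full synthetic-cohort radiomics pipeline
#'
#' simulate -> segment -> fit-pk -> extract -> reduce -> model ->
#' evaluate, for every task in the configuration. With an output directory
#' the run writes `features.csv`, `labels.csv`, per-task
#' `reduced_<task>.json`, `auc_curve_<task>.csv`, `model_<task>.json`,
#' `univariate_<task>.csv` and a `manifest.json` recording parameters and
#' seeds. Identical config and seed give identical outputs.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed optional master-seed override.
#' @return A list with `features` (data.frame), `labels`, and `results`
#'   (per task: `reduced`, `curve`, `model`, `univariate`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  tmpl <- do.call(phantom_spec,
                  c(list(noise_sd = config$noise_sd), config$template_args))
  cspec <- cohort_spec(n_lesions = config$n_lesions,
                       class_balance = config$class_balance,
                       tasks = config$tasks,
                       effect_map = config$effect_map,
                       lesion_sd = config$lesion_sd,
                       template = tmpl,
                       seed = .derive_seed(config$seed, 11L))
  cohort <- generate_cohort(cspec)

  feats <- lapply(cohort$phantoms, lesion_features,
                  threshold = config$threshold,
                  iauc_window = config$iauc_window)
  fmat <- do.call(rbind, feats)
  features <- data.frame(lesion_id = names(cohort$phantoms), fmat,
                         check.names = FALSE, row.names = NULL,
                         stringsAsFactors = FALSE)

  results <- list()
  for (task in config$tasks) {
    lab <- cohort$labels[cohort$labels$task == task, ]
    y <- lab$label[match(features$lesion_id, lab$lesion_id)]
    reduced <- reduce_features(fmat, y, k = config$k,
                               n_boot = config$n_boot, delta = config$delta,
                               seed = .derive_seed(config$seed, 21L),
                               outcome_name = task)
    curve <- build_models(reduced, fmat, y, max_order = config$max_order,
                          n_boot = config$n_boot,
                          seed = .derive_seed(config$seed, 31L))
    model <- select_final_model(curve, fmat, y, n_boot = config$n_boot,
                                seed = .derive_seed(config$seed, 41L),
                                outcome_name = task)
    uni <- univariate_analysis(reduced, fmat, y)
    results[[task]] <- list(reduced = reduced, curve = curve,
                            model = model, univariate = uni)
  }

  out <- list(features = features, labels = cohort$labels,
              results = results, config = config)
  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(run$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  for (task in names(run$results)) {
    res <- run$results[[task]]
    jsonlite::write_json(
      list(outcome = task, features = res$reduced$features,
           gains = res$reduced$gains, rho = res$reduced$rho),
      file.path(out_dir, paste0("reduced_", task, ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(order = res$curve$orders,
                                auc = res$curve$auc),
                     file.path(out_dir, paste0("auc_curve_", task, ".csv")),
                     row.names = FALSE)
    write_model(res$model, file.path(out_dir, paste0("model_", task, ".json")))
    utils::write.csv(res$univariate,
                     file.path(out_dir, paste0("univariate_", task, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(package = "dceradiomics",
                   version = as.character(utils::packageVersion("dceradiomics")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = unclass(run$config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Serialize / deserialize a logistic model as JSON
#'
#' @param model a `logistic_model`.
#' @param path JSON file path.
#' @return `write_model`: the path, invisibly. `read_model`: the model.
#' @export
write_model <- function(model, path) {
  obj <- list(outcome = model$outcome, order = model$order,
              features = model$features,
              coefficients = as.list(model$coefficients),
              intercept = model$intercept,
              coefficients_std = as.list(model$coefficients_std),
              intercept_std = model$intercept_std,
              transform = list(mu = as.list(model$transform$mu),
                               sd = as.list(model$transform$sd)),
              performance = list(auc = model$performance$auc,
                                 auc_se = model$performance$auc_se,
                                 sensitivity = model$performance$sensitivity,
                                 specificity = model$performance$specificity,
                                 accuracy = model$performance$accuracy))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(outcome = obj$outcome, order = obj$order,
                 features = obj$features,
                 coefficients = unlist(obj$coefficients),
                 intercept = obj$intercept,
                 coefficients_std = unlist(obj$coefficients_std),
                 intercept_std = obj$intercept_std,
                 transform = list(mu = unlist(obj$transform$mu),
                                  sd = unlist(obj$transform$sd)),
                 performance = obj$performance),
            class = "logistic_model")
}
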