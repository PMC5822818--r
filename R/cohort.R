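#' Labeled synthetic cohort specification
#'
#' Describes a cohort of lesion phantoms with binary outcome labels and
#' planted associations: for each task, positive-class lesions have their
#' pharmacokinetic parameters multiplied by the task's `effect_map` entries.
#' Between-lesion biological variability is log-normal around the template
#' phantom's truth values.
#'
#' @param n_lesions number of lesions (>= 4).
#' @param class_balance fraction of positive labels per task, in (0, 1);
#'   scalar (recycled) or named by task.
#' @param tasks character vector of outcome names.
#' @param effect_map named list, one entry per task, each a named numeric
#'   vector of multiplicative shifts applied to `ktrans` and/or `kep` in the
#'   positive class (e.g. `list(ki67 = c(ktrans = 1.6))`). 1 = null effect.
#' @param lesion_sd log-normal sd of between-lesion parameter variability.
#' @param template a [phantom_spec()] giving acquisition and baseline truth
#'   shared by all lesions.
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lesions = 40, class_balance = 0.5,
                        tasks = c("ki67", "grade"),
                        effect_map = list(ki67 = c(ktrans = 1.6),
                                          grade = c(kep = 1.5)),
                        lesion_sd = 0.15, template = phantom_spec(),
                        seed = 1L) {
  if (n_lesions < 4L)
    stop("cohort_spec: need at least 4 lesions", call. = FALSE)
  bal <- if (length(class_balance) == 1L)
    stats::setNames(rep(class_balance, length(tasks)), tasks)
  else class_balance[tasks]
  if (any(is.na(bal)) || any(bal <= 0) || any(bal >= 1))
    stop("cohort_spec: class_balance must be in (0, 1) for every task",
         call. = FALSE)
  npos <- round(bal * n_lesions)
  if (any(npos < 2L) || any(n_lesions - npos < 2L))
    stop("cohort_spec: every task needs >= 2 lesions per class",
         call. = FALSE)
  missing_fx <- setdiff(tasks, names(effect_map))
  if (length(missing_fx))
    effect_map[missing_fx] <- list(numeric(0))
  structure(list(n_lesions = as.integer(n_lesions), class_balance = bal,
                 tasks = tasks, effect_map = effect_map,
                 lesion_sd = lesion_sd, template = template,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labeled phantom cohort
#'
#' Draws per-lesion pharmacokinetic parameters (log-normal around the
#' template truth), assigns exact-count binary labels per task, applies the
#' planted multiplicative effects to positive-class lesions, and simulates
#' one phantom per lesion. The whole draw is reproducible under `seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `phantoms` (list of [simulate_phantom()] outputs) and
#'   `labels` (long-format data.frame with columns `lesion_id`, `task`,
#'   `label`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_lesions
  set.seed(spec$seed)

  labels <- lapply(spec$tasks, function(task) {
    npos <- round(spec$class_balance[[task]] * n)
    lab <- integer(n)
    lab[sample.int(n, npos)] <- 1L
    data.frame(lesion_id = sprintf("lesion_%03d", seq_len(n)),
               task = task, label = lab, stringsAsFactors = FALSE)
  })
  labels <- do.call(rbind, labels)

  base_kt <- spec$template$true_ktrans * exp(stats::rnorm(n, 0, spec$lesion_sd))
  base_kep <- spec$template$true_kep * exp(stats::rnorm(n, 0, spec$lesion_sd))
  lesion_seeds <- sample.int(.Machine$integer.max, n)

  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    kt <- base_kt[i]; kep <- base_kep[i]
    for (task in spec$tasks) {
      lab <- labels$label[labels$task == task][i]
      if (lab == 1L) {
        fx <- spec$effect_map[[task]]
        if (!is.null(fx["ktrans"]) && !is.na(fx["ktrans"])) kt <- kt * fx[["ktrans"]]
        if (!is.null(fx["kep"]) && !is.na(fx["kep"])) kep <- kep * fx[["kep"]]
      }
    }
    kep <- max(kep, kt)   # keep ve <= 1
    ps <- spec$template
    ps$true_ktrans <- kt
    ps$true_kep <- kep
    ps$seed <- lesion_seeds[i]
    phantoms[[i]] <- simulate_phantom(ps)
  }
  names(phantoms) <- sprintf("lesion_%03d", seq_len(n))
  list(phantoms = phantoms, labels = labels)
}
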