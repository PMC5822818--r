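#' Arterial input function models
#'
#' Plasma contrast concentration Cp(t) driving the Tofts model. The default
#' is the classical biexponential population AIF
#' \deqn{Cp(t) = D (a_1 e^{-m_1 t} + a_2 e^{-m_2 t})}
#' with dose D in mmol/kg, amplitudes in mM kg/L and decay rates in 1/min,
#' evaluated on time since contrast arrival. A constant model (plateau level
#' after onset) and a custom sampled curve are also available.
#'
#' @param model_id one of `"biexponential"`, `"constant"`, `"custom"`.
#' @param dose contrast dose (mmol/kg); default 0.1.
#' @param a1,a2 amplitudes (mM kg/L); defaults 3.99 and 4.78.
#' @param m1,m2 decay rates (1/min); defaults 0.144 and 0.0111. Must be > 0.
#' @param onset_time contrast arrival time (s); Cp = 0 before it.
#' @param level plateau concentration (mM) for the constant model.
#' @param sample_times,sample_values sampled curve for the custom model;
#'   times in s since onset, values in mM (linearly interpolated).
#' @return An object of class `aif_model`.
#' @export
aif_model <- function(model_id = c("biexponential", "constant", "custom"),
                      dose = 0.1, a1 = 3.99, a2 = 4.78,
                      m1 = 0.144, m2 = 0.0111, onset_time = 0,
                      level = 1, sample_times = NULL, sample_values = NULL) {
  model_id <- match.arg(model_id)
  if (model_id == "biexponential" && (m1 <= 0 || m2 <= 0))
    stop("aif_model: decay rates must be positive", call. = FALSE)
  if (model_id == "custom") {
    if (is.null(sample_times) || is.null(sample_values) ||
        length(sample_times) != length(sample_values))
      stop("aif_model: custom model needs matching sample_times/sample_values",
           call. = FALSE)
    if (any(sample_values < 0))
      stop("aif_model: custom AIF values must be non-negative", call. = FALSE)
  }
  structure(list(model_id = model_id, dose = dose, a1 = a1, a2 = a2,
                 m1 = m1, m2 = m2, onset_time = onset_time, level = level,
                 sample_times = sample_times, sample_values = sample_values),
            class = "aif_model")
}

#' Sample an AIF on a time grid
#'
#' @param model an [aif_model()].
#' @param times strictly increasing acquisition times (s).
#' @return Plasma concentration (mM) at each time; zero before onset.
#' @export
generate_aif <- function(model, times) {
  stopifnot(inherits(model, "aif_model"))
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("generate_aif: `times` must be strictly increasing", call. = FALSE)
  tau_min <- (times - model$onset_time) / 60   # minutes since arrival
  cp <- switch(model$model_id,
    biexponential = model$dose *
      (model$a1 * exp(-model$m1 * tau_min) + model$a2 * exp(-model$m2 * tau_min)),
    constant = rep(model$level, length(times)),
    custom = stats::approx(model$sample_times, model$sample_values,
                           xout = times - model$onset_time, rule = 2)$y
  )
  cp[times < model$onset_time] <- 0
  pmax(cp, 0)
}
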