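#' Tidy a trained volume model
#'
#' @param x A `resp_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `imu`, `family`
#'   inferred from the term name, plus `compartment` and `model`.
#' @method tidy resp_fit
#' @export
tidy.resp_fit <- function(x, ...) {
  nm <- names(x$coefficients)
  tibble(
    term = nm,
    estimate = unname(x$coefficients),
    imu = as.integer(sub("^[kh](\\d+).*$", "\\1", nm)),
    compartment = x$compartment,
    model = x$model
  )
}

#' @rdname tidy.resp_fit
#' @method glance resp_fit
#' @export
glance.resp_fit <- function(x, ...) {
  tibble(
    model = x$model, compartment = x$compartment,
    objective = x$objective, init_objective = x$init_objective,
    n_trials = x$n_trials, evaluations = x$evaluations,
    converged = x$converged
  )
}

#' Tidy a LOOCV report
#'
#' @param x A `resp_loocv`.
#' @param ... Unused.
#' @return The per-trial, per-compartment error tibble (signed relative
#'   errors in percent, with measured and estimated parameters).
#' @method tidy resp_loocv
#' @export
tidy.resp_loocv <- function(x, ...) x$errors

#' @rdname tidy.resp_loocv
#' @method glance resp_loocv
#' @export
glance.resp_loocv <- function(x, ...) {
  summarize_cohort(x$errors, by = c("compartment", "model")) %>%
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd", "abs_mean", "mean_abs"))
}

#' Tidy a sensor-selection result
#'
#' @param x A `resp_selection`.
#' @param ... Unused.
#' @return The selection tibble (family, target, imu, mean absolute
#'   loading, selected flag).
#' @method tidy resp_selection
#' @export
tidy.resp_selection <- function(x, ...) as_tibble(unclass(x))
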