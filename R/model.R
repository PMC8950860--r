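#' IMU-based volume model definitions
#'
#' Two fixed linear, mass-scaled models relate IMU signals to compartmental
#' volumes. Model 1 uses the 3D acceleration norm (`A_ToT`) of IMUs 7 and 9
#' for CW and RC, and of IMUs 5, 7 and 9 for AB (seven coefficients
#' `k7CW, k9CW, k7RC, k9RC, k5AB, k7AB, k9AB`). Model 2 uses the
#' Y-acceleration (`A_Y`) of IMUs 7 and 9 for all three compartments (six
#' coefficients `h7CW ... h9AB`).
#'
#' @param model 1 or 2.
#' @return List of class `resp_model_def`: `model`, `coef_prefix`,
#'   `regressors` (per compartment, a tibble with `imu` and `family`).
#' @export
model_definition <- function(model = 1) {
  model <- as.integer(model)
  if (!model %in% c(1L, 2L)) abort("model must be 1 or 2.")
  reg <- if (model == 1L) {
    list(
      CW = tibble(imu = c(7L, 9L), family = "A_ToT"),
      RC = tibble(imu = c(7L, 9L), family = "A_ToT"),
      AB = tibble(imu = c(5L, 7L, 9L), family = "A_ToT")
    )
  } else {
    list(
      CW = tibble(imu = c(7L, 9L), family = "A_Y"),
      RC = tibble(imu = c(7L, 9L), family = "A_Y"),
      AB = tibble(imu = c(7L, 9L), family = "A_Y")
    )
  }
  structure(
    list(model = model, coef_prefix = if (model == 1L) "k" else "h",
         regressors = reg),
    class = "resp_model_def"
  )
}

coef_names <- function(def, compartment) {
  r <- def$regressors[[compartment]]
  paste0(def$coef_prefix, r$imu, compartment)
}

imu_signal <- function(imus, imu, family) {
  pre <- paste0("imu", imu, "_")
  switch(family,
    A_X = imus[[paste0(pre, "ax")]],
    A_Y = imus[[paste0(pre, "ay")]],
    A_Z = imus[[paste0(pre, "az")]],
    A_ToT = sqrt(imus[[paste0(pre, "ax")]]^2 + imus[[paste0(pre, "ay")]]^2 +
                   imus[[paste0(pre, "az")]]^2),
    abort(paste0("Unsupported signal family: ", family))
  )
}

#' Assemble model regressors for one trial
#'
#' Extracts the model's IMU signals from an aligned trial, low-pass filters
#' them at the model cut-off (zero-lag) and demeans them over the analysis
#' segment.
#'
#' @param trial Aligned `resp_trial`.
#' @param model A `resp_model_def` (or 1/2).
#' @param config A [resp_config()].
#' @return Named list (CW, RC, AB) of T x p regressor matrices; column names
#'   are the coefficient names.
#' @export
assemble_regressors <- function(trial, model = model_definition(1),
                                config = resp_config()) {
  if (is.numeric(model)) model <- model_definition(model)
  if (!isTRUE(trial$aligned)) abort("Trial must be aligned first (align_trial).")
  rate <- config$imu_rate
  lp <- function(x) {
    y <- lowpass_zero_lag(tibble(time = seq_along(x) / rate, v = x),
                          config$model_cutoff, config$filter_order, rate = rate)$v
    y - mean(y)
  }
  out <- imap(model$regressors, function(r, comp) {
    X <- vapply(seq_len(nrow(r)),
                function(i) lp(imu_signal(trial$imus, r$imu[i], r$family[i])),
                numeric(nrow(trial$imus)))
    colnames(X) <- coef_names(model, comp)
    X
  })
  out
}

#' Predict compartmental volumes from model coefficients
#'
#' Implements the mass-scaled linear model: per compartment,
#' `V(t) = mass * sum_j coef_j * regressor_j(t)`.
#'
#' @param coeffs Named numeric vector of coefficients (as trained), or a
#'   `resp_coefset` from [run_loocv()]/[train_coefficients()].
#' @param regressors Per-compartment regressor matrices from
#'   [assemble_regressors()].
#' @param mass Body mass (kg).
#' @param time Optional time vector for the output tibble.
#' @return A `resp_volumes` tibble of the estimated (demeaned) volumes.
#' @export
predict_volume <- function(coeffs, regressors, mass, time = NULL) {
  est <- imap(regressors, function(X, comp) {
    k <- coeffs[colnames(X)]
    if (anyNA(k)) abort(sprintf("Missing coefficient(s) for compartment %s.", comp))
    mass * as.vector(X %*% k)
  })
  n <- length(est[[1]])
  out <- tibble(
    time = if (is.null(time)) seq_len(n) else time,
    V_CW = est$CW, V_RC = est$RC, V_AB = est$AB
  )
  class(out) <- c("resp_volumes", class(out))
  out
}

#' Root-mean-square difference between two volume series
#'
#' @param measured,estimated Numeric vectors of equal length (L).
#' @return RMSD in litres.
#' @export
rmsd <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated))
  sqrt(mean((measured - estimated)^2))
}

# sufficient statistics of one trial for one compartment: the per-trial
# squared RMSD is (c0 - 2 k'b + k'G k), all divided by T already
trial_gram <- function(X, v, mass) {
  list(c0 = sum(v * v) / length(v),
       b = as.vector(crossprod(X, v)) * mass / length(v),
       G = crossprod(X) * mass^2 / length(v))
}

objective_from_grams <- function(k, grams) {
  sq <- vapply(grams, function(g) {
    max(0, g$c0 - 2 * sum(k * g$b) + sum(k * (g$G %*% k)))
  }, numeric(1))
  sqrt(sum(sq))
}

#' Train model coefficients on a set of trials
#'
#' Minimises the Euclidean norm of the vector of per-trial RMSDs between
#' measured and estimated volumes, one entry per (subject, repetition).
#' The squared objective is a weighted least-squares criterion (weights
#' 1/T per trial), so the search is initialised at the closed-form WLS
#' solution and refined by derivative-free Nelder-Mead simplex
#' minimisation; the simplex step verifies (and can only improve on) the
#' initialisation.
#'
#' @param trials List of per-trial inputs, each a list with elements `X`
#'   (T x p regressor matrix), `v` (demeaned measured volume, length T) and
#'   `mass` (kg). See [prepare_cohort()].
#' @param model A `resp_model_def` (for bookkeeping; may be NULL).
#' @param compartment `"CW"`, `"RC"` or `"AB"`.
#' @param reltol,maxit Simplex convergence tolerance and evaluation cap.
#' @return List of class `resp_fit`: `coefficients`, `objective` (norm of
#'   the RMSD vector, L), `rmsd_per_trial` (L), `init` (WLS start),
#'   `init_objective`, `evaluations`, `converged`, `model`, `compartment`,
#'   `n_trials`.
#' @export
train_coefficients <- function(trials, model = NULL, compartment = "CW",
                               reltol = 1e-9, maxit = 1e5) {
  if (length(trials) < 2) abort("Training requires at least 2 trials.")
  grams <- lapply(trials, function(tr) trial_gram(tr$X, tr$v, tr$mass))
  p <- length(grams[[1]]$b)
  G <- Reduce(`+`, lapply(grams, `[[`, "G"))
  b <- Reduce(`+`, lapply(grams, `[[`, "b"))
  wls <- tryCatch(as.vector(solve(G, b)), error = function(e) {
    # collinear regressors (e.g. noise-free duplicated channels): fall back
    # to the minimal-norm solution via the pseudoinverse
    sv <- svd(G)
    pos <- sv$d > max(sv$d) * 1e-12
    as.vector(sv$v[, pos, drop = FALSE] %*%
                ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
  })
  f <- function(k) objective_from_grams(k, grams)
  opt <- optim(wls, f, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
  # 0 = converged; 10 = simplex degeneracy, which occurs when the WLS start
  # is already the optimum and the simplex collapses onto it
  if (!opt$convergence %in% c(0L, 10L)) {
    abort(sprintf("Simplex search did not converge (code %d) after %d evaluations.",
                  opt$convergence, opt$counts[1]))
  }
  best <- if (opt$value <= f(wls)) opt$par else wls
  nm <- colnames(trials[[1]]$X)
  coefs <- setNames(best, nm)
  per_trial <- vapply(grams, function(g) {
    sqrt(max(0, g$c0 - 2 * sum(best * g$b) + sum(best * (g$G %*% best))))
  }, numeric(1))
  structure(
    list(coefficients = coefs, objective = f(best),
         rmsd_per_trial = per_trial,
         init = setNames(wls, nm), init_objective = f(wls),
         evaluations = unname(opt$counts[1]), converged = TRUE,
         model = if (!is.null(model)) model$model else NA_integer_,
         compartment = compartment, n_trials = length(trials)),
    class = "resp_fit"
  )
}

#' @export
print.resp_fit <- function(x, ...) {
  cat(sprintf("<resp_fit> model %s, compartment %s: objective %.4g L over %d trials\n",
              x$model, x$compartment, x$objective, x$n_trials))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Preprocess a cohort for modelling
#'
#' Aligns every trial, computes the plethysmographic volume series, and
#' caches the low-pass-filtered, demeaned volumes and model regressors.
#' Used by [run_loocv()] so that both models share one preprocessing pass.
#'
#' @param cohort A `resp_cohort`.
#' @param config A [resp_config()].
#' @return List of per-trial records: `subject_id`, `repetition`, `sex`,
#'   `mass`, `time`, `vols` (T x 3 demeaned matrix, columns CW/RC/AB),
#'   `reg1`, `reg2` (regressor sets for the two models).
#' @export
prepare_cohort <- function(cohort, config = cohort$config %||% resp_config()) {
  defs <- list(model_definition(1), model_definition(2))
  map(cohort$trials, function(trial) {
    al <- align_trial(trial, config)
    vols <- compute_volume_series(al$markers)
    rate <- config$imu_rate
    lp <- function(x) {
      y <- lowpass_zero_lag(tibble(time = seq_along(x) / rate, v = x),
                            config$model_cutoff, config$filter_order, rate = rate)$v
      y - mean(y)
    }
    V <- cbind(CW = lp(vols$V_CW), RC = lp(vols$V_RC), AB = lp(vols$V_AB))
    list(subject_id = al$subject_id, repetition = al$repetition, sex = al$sex,
         mass = al$body_mass, time = vols$time, vols = V,
         reg1 = assemble_regressors(al, defs[[1]], config),
         reg2 = assemble_regressors(al, defs[[2]], config))
  })
}

#' Subject-level leave-one-out cross-validation
#'
#' For each subject: trains the model's three compartments on all other
#' subjects' trials (both repetitions), predicts the held-out subject's
#' volume series for both repetitions, extracts the respiratory parameters
#' from the measured and estimated series, and records the relative errors.
#'
#' @param cohort A `resp_cohort` (>= 3 subjects).
#' @param model 1, 2 or a `resp_model_def`.
#' @param config A [resp_config()].
#' @param prepared Optional output of [prepare_cohort()] to reuse.
#' @return List of class `resp_loocv`: `model`, `folds` (per subject:
#'   coefficient sets and objectives per compartment), `errors` (tidy
#'   tibble: subject, repetition, sex, compartment, measured and estimated
#'   parameters, relative errors dRR/dDI/dDE/dVI/dVE in %), `config`.
#' @export
run_loocv <- function(cohort, model = 1, config = cohort$config %||% resp_config(),
                      prepared = NULL) {
  def <- if (inherits(model, "resp_model_def")) model else model_definition(model)
  reg_slot <- if (def$model == 1L) "reg1" else "reg2"
  if (is.null(prepared)) prepared <- prepare_cohort(cohort, config)
  subjects <- unique(vapply(prepared, `[[`, "", "subject_id"))
  if (length(subjects) < 3) abort("LOOCV requires at least 3 subjects.")

  folds <- list(); err_rows <- list()
  for (s in subjects) {
    held <- keep(prepared, ~ .x$subject_id == s)
    train <- keep(prepared, ~ .x$subject_id != s)
    fits <- lapply(c(CW = "CW", RC = "RC", AB = "AB"), function(comp) {
      train_coefficients(
        lapply(train, function(tr) {
          list(X = tr[[reg_slot]][[comp]], v = tr$vols[, comp], mass = tr$mass)
        }),
        model = def, compartment = comp
      )
    })
    coefs <- unlist(lapply(fits, `[[`, "coefficients"))
    names(coefs) <- unlist(lapply(fits, function(f) names(f$coefficients)))
    folds[[s]] <- list(subject_id = s, fits = fits, coefficients = coefs)

    for (tr in held) {
      est <- predict_volume(coefs, tr[[reg_slot]], tr$mass, time = tr$time)
      for (comp in c("CW", "RC", "AB")) {
        meas_p <- tryCatch(
          respiratory_parameters(
            segment_breaths(tr$vols[, comp], config$imu_rate, config)),
          error = function(e) NULL)
        est_p <- tryCatch(
          respiratory_parameters(
            segment_breaths(est[[paste0("V_", comp)]], config$imu_rate, config)),
          error = function(e) NULL)
        if (is.null(meas_p) || is.null(est_p)) next
        err_rows[[length(err_rows) + 1L]] <- bind_cols(
          tibble(subject_id = tr$subject_id, repetition = tr$repetition,
                 sex = tr$sex, model = def$model, compartment = comp),
          setNames(meas_p[c("RR", "DI", "DE", "VI", "VE")],
                   paste0("meas_", c("RR", "DI", "DE", "VI", "VE"))),
          setNames(est_p[c("RR", "DI", "DE", "VI", "VE")],
                   paste0("est_", c("RR", "DI", "DE", "VI", "VE"))),
          relative_errors(meas_p, est_p)
        )
      }
    }
  }
  structure(
    list(model = def$model, folds = folds, errors = bind_rows(err_rows),
         config = config),
    class = "resp_loocv"
  )
}

#' @export
print.resp_loocv <- function(x, ...) {
  cat(sprintf("<resp_loocv> model %d: %d folds, %d trial x compartment rows\n",
              x$model, length(x$folds), nrow(x$errors)))
  invisible(x)
}
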