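# synthetic per-trial training inputs built directly from the model
# structure: X columns are smooth band-limited signals, v = mass * X k + noise
make_training_set <- function(n_trials, k_true, mass = NULL, T_ = 600,
                              noise = 0, equal_length = TRUE, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      Ti <- if (equal_length) T_ else T_ + sample(-100:100, 1)
      t <- (1:Ti) / 100
      X <- sapply(seq_along(k_true), function(j) {
        sin(2 * pi * runif(1, 0.2, 0.3) * t + runif(1, 0, 2 * pi))
      })
      colnames(X) <- paste0("k", seq_along(k_true), "CW")
      m <- if (is.null(mass)) runif(1, 50, 90) else mass
      v <- m * as.vector(X %*% k_true) + rnorm(Ti, 0, noise)
      list(X = X, v = v, mass = m)
    })
  })
}

test_that("model definitions encode the fixed regressor lists", {
  m1 <- model_definition(1)
  expect_equal(m1$regressors$CW$imu, c(7L, 9L))
  expect_equal(m1$regressors$RC$imu, c(7L, 9L))
  expect_equal(m1$regressors$AB$imu, c(5L, 7L, 9L))
  expect_true(all(unlist(lapply(m1$regressors, `[[`, "family")) == "A_ToT"))
  expect_length(unlist(lapply(c("CW", "RC", "AB"),
                              function(cp) respimu:::coef_names(m1, cp))), 7L)

  m2 <- model_definition(2)
  for (cp in c("CW", "RC", "AB")) {
    expect_equal(m2$regressors[[cp]]$imu, c(7L, 9L))
    expect_true(all(m2$regressors[[cp]]$family == "A_Y"))
  }
  expect_length(unlist(lapply(c("CW", "RC", "AB"),
                              function(cp) respimu:::coef_names(m2, cp))), 6L)
  expect_error(model_definition(3), "1 or 2")
})

test_that("assembled regressors are demeaned, band-limited and correctly counted", {
  co <- tiny_cohort()
  prep <- tiny_prepared()
  cfg <- co$config
  al <- align_trial(co$trials[[1]], cfg)
  reg2 <- assemble_regressors(al, model_definition(2), cfg)
  for (cp in c("CW", "RC", "AB")) {
    expect_equal(ncol(reg2[[cp]]), 2L)
    expect_lt(max(abs(colMeans(reg2[[cp]]))), 1e-10)
  }
  # a 5 Hz component injected into imu7_ay is attenuated >= 24 dB at 2.5 Hz
  al2 <- al
  n <- nrow(al2$imus)
  tone <- 0.5 * sin(2 * pi * 5 * (1:n) / 100)
  al2$imus$imu7_ay <- al2$imus$imu7_ay + tone
  r0 <- assemble_regressors(al, model_definition(2), cfg)$CW[, 1]
  r1 <- assemble_regressors(al2, model_definition(2), cfg)$CW[, 1]
  leak <- r1 - r0
  att_db <- -20 * log10((max(leak[300:(n - 300)]) - min(leak[300:(n - 300)])) / 2 / 0.5)
  expect_gte(att_db, 24)
})

test_that("volume prediction implements the mass-scaled linear combination", {
  reg <- list(CW = cbind(k7CW = rep(1, 5), k9CW = rep(1, 5)),
              RC = cbind(k7RC = rep(0, 5), k9RC = rep(0, 5)),
              AB = cbind(k5AB = rep(1, 5), k7AB = rep(0, 5), k9AB = rep(0, 5)))
  coefs <- c(k7CW = 0.001, k9CW = 0.002, k7RC = 1, k9RC = 1,
             k5AB = 0.01, k7AB = 5, k9AB = 5)
  est <- predict_volume(coefs, reg, mass = 70)
  expect_equal(est$V_CW, rep(70 * 0.003, 5))   # 0.21 L
  expect_equal(est$V_RC, rep(0, 5))
  expect_equal(est$V_AB, rep(0.7, 5))
  est2 <- predict_volume(coefs, reg, mass = 140)
  expect_equal(est2$V_CW, 2 * est$V_CW)
  zero <- predict_volume(setNames(rep(0, 7), names(coefs)), reg, mass = 70)
  expect_true(all(zero$V_CW == 0))
})

test_that("rmsd matches closed forms", {
  x <- sin(seq(0, 20, by = 0.01))
  expect_equal(rmsd(x, x), 0)
  expect_equal(rmsd(x, x + 0.5), 0.5)
  t <- seq(0, 99.99, by = 0.01)
  s <- 0.8 * sin(2 * pi * 0.25 * t)
  expect_equal(rmsd(s, rep(0, length(s))), 0.8 / sqrt(2), tolerance = 1e-3)
})

test_that("training recovers known coefficients exactly on noise-free data", {
  k_true <- c(0.004, -0.002, 0.001)
  trials <- make_training_set(6, k_true, noise = 0, seed = 3)
  fit <- train_coefficients(trials, compartment = "CW")
  expect_equal(unname(fit$coefficients), k_true, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-6)
  expect_length(fit$rmsd_per_trial, 6L)
})

test_that("simplex result matches the stacked weighted least-squares oracle", {
  k_true <- c(0.004, -0.002)
  trials <- make_training_set(8, k_true, noise = 0.3, equal_length = FALSE,
                              seed = 9)
  fit <- train_coefficients(trials, compartment = "CW")
  # independent oracle: stack rows weighted by mass/sqrt(T) and solve by QR
  rows <- lapply(trials, function(tr) {
    w <- 1 / sqrt(length(tr$v))
    list(X = tr$X * tr$mass * w, v = tr$v * w)
  })
  Xs <- do.call(rbind, lapply(rows, `[[`, "X"))
  vs <- do.call(c, lapply(rows, `[[`, "v"))
  k_wls <- stats::lm.fit(Xs, vs)$coefficients
  obj <- function(k) {
    sqrt(sum(vapply(trials, function(tr) {
      mean((tr$v - tr$mass * as.vector(tr$X %*% k))^2)
    }, numeric(1))))
  }
  expect_equal(fit$objective, obj(k_wls), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(k_wls), tolerance = 1e-4)
  # the simplex refinement never worsens its initialisation
  expect_lte(fit$objective, fit$init_objective + 1e-12)
})

test_that("with equal-length trials the stacked plain OLS solution coincides", {
  k_true <- c(0.003, 0.001)
  trials <- make_training_set(5, k_true, noise = 0.2, equal_length = TRUE,
                              seed = 12)
  fit <- train_coefficients(trials, compartment = "CW")
  Xs <- do.call(rbind, lapply(trials, function(tr) tr$X * tr$mass))
  vs <- do.call(c, lapply(trials, `[[`, "v"))
  k_ols <- stats::lm.fit(Xs, vs)$coefficients
  expect_equal(unname(fit$coefficients), unname(k_ols), tolerance = 1e-5)
})

test_that("LOOCV folds exclude the held-out subject and cover the cohort", {
  co <- tiny_cohort()
  res <- run_loocv(co, 2, prepared = tiny_prepared())
  expect_length(res$folds, 3L)
  expect_setequal(unique(res$errors$subject_id), co$subjects$subject_id)
  expect_equal(nrow(res$errors), 3L * 3L)  # 3 trials x 3 compartments
  expect_true(all(c("dRR", "dDI", "dDE", "dVI", "dVE") %in% names(res$errors)))
  # each fold trained on the other subjects only
  expect_length(res$folds[["S01"]]$fits$CW$rmsd_per_trial, 2L)
})

test_that("shuffling subject order leaves the multiset of fold errors unchanged", {
  co <- tiny_cohort()
  prep <- tiny_prepared()
  res <- run_loocv(co, 2, prepared = prep)
  res_shuf <- run_loocv(co, 2, prepared = rev(prep))
  expect_equal(sort(res$errors$dVI), sort(res_shuf$errors$dVI), tolerance = 1e-10)
})

test_that("identical noise-free subjects give near-zero held-out errors", {
  # a whisper of sensor noise keeps the two lateral channels from being
  # exactly collinear; errors should still be essentially zero
  cfg <- noisefree_config(seed = 6, duration = 45, accel_noise_sd = 1e-5)
  subj <- withr::with_seed(6, generate_subject_params(cfg, n = 1, sex = "M"))
  trials <- lapply(1:3, function(i) {
    g <- generate_trial(subj, cfg, repetition = 1L, seed = 100 + i)
    tr <- g$trial
    tr$subject_id <- sprintf("S%02d", i)
    tr
  })
  co <- structure(list(
    subjects = dplyr::bind_rows(subj, subj, subj),
    trials = setNames(trials, sprintf("S%02d_r1", 1:3)),
    truths = NULL, config = cfg
  ), class = "resp_cohort")
  res <- run_loocv(co, 2, config = cfg)
  # exchangeability: every held-out subject sees nearly the same error
  # (trials differ only in their random clock offsets, hence window cropping)
  for (comp in c("CW", "RC", "AB")) {
    dvi <- res$errors$dVI[res$errors$compartment == comp]
    expect_lt(diff(range(dvi)), 0.5)
  }
  # residual error reflects only the mild tilt-projection nonlinearity
  expect_lt(max(abs(res$errors$dVI)), 3)
  expect_lt(max(abs(res$errors$dRR)), 0.5)
})

test_that("tidy and glance expose fits and LOOCV reports", {
  k_true <- c(0.004, -0.002)
  trials <- make_training_set(4, k_true, noise = 0.1, seed = 2)
  fit <- train_coefficients(trials, model = model_definition(1),
                            compartment = "CW")
  td <- tidy(fit)
  expect_equal(nrow(td), 2L)
  expect_equal(td$imu, c(1L, 2L))  # parsed from coefficient names
  gl <- glance(fit)
  expect_equal(gl$n_trials, 4L)

  res <- run_loocv(tiny_cohort(), 2, prepared = tiny_prepared())
  expect_identical(tidy(res), res$errors)
  expect_equal(nrow(glance(res)), 3L)
})
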