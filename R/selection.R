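FAMILY_TAGS <- c("A_X", "A_Y", "A_Z", "A_ToT",
                 "Omega_X", "Omega_Y", "Omega_Z", "Omega_ToT")

#' Homologous signal matrices across the IMU network
#'
#' Pools each signal family across the nine IMUs into a T x 9 matrix:
#' the three acceleration components, the three angular-velocity components,
#' and the per-sample Euclidean norms of each (`A_ToT`, `Omega_ToT`).
#'
#' @param imus IMU tibble (`time` + `imu<j>_{ax..gz}` columns), typically the
#'   analysis segment of an aligned trial.
#' @return Named list of eight T x 9 matrices (columns `imu1` ... `imu9`),
#'   each with a `family` attribute.
#' @export
build_homologous_matrices <- function(imus) {
  comp <- list(A_X = "ax", A_Y = "ay", A_Z = "az",
               Omega_X = "gx", Omega_Y = "gy", Omega_Z = "gz")
  get9 <- function(suffix) {
    m <- as.matrix(imus[paste0("imu", 1:9, "_", suffix)])
    colnames(m) <- paste0("imu", 1:9)
    m
  }
  out <- lapply(comp, get9)
  ax <- out$A_X; ay <- out$A_Y; az <- out$A_Z
  out$A_ToT <- sqrt(ax^2 + ay^2 + az^2)
  gx <- out$Omega_X; gy <- out$Omega_Y; gz <- out$Omega_Z
  out$Omega_ToT <- sqrt(gx^2 + gy^2 + gz^2)
  out <- out[FAMILY_TAGS]
  for (f in FAMILY_TAGS) attr(out[[f]], "family") <- f
  out
}

#' Z-score the columns of a homologous matrix
#'
#' @param matrix T x 9 homologous matrix.
#' @return Matrix with every column standardised to mean 0, SD 1 (the
#'   `family` attribute is preserved).
#' @export
zscore_columns <- function(matrix) {
  sds <- apply(matrix, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(matrix)[sds == 0]
    abort(sprintf("Constant column(s) cannot be z-scored: %s (family %s).",
                  paste(bad, collapse = ", "),
                  attr(matrix, "family") %||% "?"))
  }
  out <- scale(matrix)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "family") <- attr(matrix, "family")
  out
}

#' PCA with correlation-scaled loadings
#'
#' Eigendecomposition of the correlation matrix of a standardised signal
#' matrix. Loadings are scaled as eigenvector x sqrt(eigenvalue), so each
#' loading equals the Pearson correlation between the observed variable and
#' the (unit-variance) PC score, and a squared loading is the fraction of
#' the variable's variance shared with that PC. Scores are mutually
#' uncorrelated with SD 1, and `scores %*% t(loadings)` reconstructs the
#' standardised input.
#'
#' @param matrix Standardised T x p matrix (see [zscore_columns()]); T > p.
#' @return List of class `resp_pca`: `loadings` (p x p), `scores` (T x p),
#'   `explained` (variance fractions, summing to 1), `family`.
#' @export
pca_loadings <- function(matrix) {
  T_ <- nrow(matrix); p <- ncol(matrix)
  if (T_ <= p) abort("PCA requires more samples than variables.")
  R <- crossprod(matrix) / (T_ - 1)
  eig <- eigen(R, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  load <- eig$vectors %*% diag(sqrt(lam), p)
  inv <- ifelse(lam > 1e-12, 1 / sqrt(lam), 0)
  scores <- matrix %*% eig$vectors %*% diag(inv, p)
  dimnames(load) <- list(colnames(matrix), paste0("PC", seq_len(p)))
  colnames(scores) <- paste0("PC", seq_len(p))
  structure(
    list(loadings = load, scores = scores, explained = lam / sum(lam),
         family = attr(matrix, "family")),
    class = "resp_pca"
  )
}

#' @export
print.resp_pca <- function(x, ...) {
  cat(sprintf("<resp_pca> family %s; explained by PC1-3: %s\n",
              x$family %||% "?",
              paste(sprintf("%.1f%%", 100 * x$explained[1:3]), collapse = ", ")))
  invisible(x)
}

#' Retain the PC best matching a respiratory volume
#'
#' Finds the PC whose score has the largest absolute Pearson correlation
#' with the (demeaned) volume channel, and flips the PC's sign (score and
#' loadings) if needed so the reported correlation is non-negative.
#'
#' @param pca A `resp_pca`.
#' @param volume Demeaned volume channel on the same time base as the scores
#'   (by convention 2.5 Hz-filtered).
#' @param scores Optional replacement score matrix (e.g. low-pass filtered
#'   copies of `pca$scores`) used for the correlation; loadings are reported
#'   from `pca` unchanged.
#' @return List of class `resp_pcmatch`: `family`, `pc` (index), `rho`
#'   (>= 0), `explained` (that PC's variance fraction), `loadings` (signed
#'   loading vector of the retained PC, sign-normalised with the score).
#' @export
best_matching_pc <- function(pca, volume, scores = NULL) {
  S <- if (is.null(scores)) pca$scores else scores
  stopifnot(nrow(S) == length(volume))
  rho <- suppressWarnings(as.vector(cor(S, volume)))
  rho[is.na(rho)] <- 0
  k <- which.max(abs(rho))
  s <- if (rho[k] < 0) -1 else 1
  structure(
    list(family = pca$family, pc = k, rho = s * rho[k],
         explained = pca$explained[k], loadings = s * pca$loadings[, k]),
    class = "resp_pcmatch"
  )
}

#' Per-trial PC matches for all families and volume targets
#'
#' For one aligned trial: builds the eight homologous matrices, z-scores
#' them, runs the PCA, and retains the best-matching PC for each of V_CW,
#' V_RC and V_AB. Correlations are computed on low-pass-filtered (model
#' cut-off), demeaned scores and volumes; the PCA itself runs on the
#' pre-filtered (10 Hz) signals.
#'
#' @param trial An aligned `resp_trial`.
#' @param volumes Optional precomputed `resp_volumes` for the trial.
#' @param config A [resp_config()].
#' @return Tibble: `subject_id`, `repetition`, `family`, `target`, `pc`,
#'   `rho`, `explained`, `imu`, `loading` (9 rows per family x target).
#' @export
trial_pc_matches <- function(trial, volumes = NULL, config = resp_config()) {
  if (!isTRUE(trial$aligned)) trial <- align_trial(trial, config)
  if (is.null(volumes)) volumes <- compute_volume_series(trial$markers)
  rate <- config$imu_rate
  lp <- function(x) {
    y <- lowpass_zero_lag(tibble(time = seq_along(x) / rate, v = x),
                          config$model_cutoff, config$filter_order, rate = rate)$v
    y - mean(y)
  }
  vols <- lapply(c(CW = "V_CW", RC = "V_RC", AB = "V_AB"),
                 function(ch) lp(volumes[[ch]]))
  mats <- build_homologous_matrices(trial$imus)
  rows <- list()
  for (fam in names(mats)) {
    pca <- pca_loadings(zscore_columns(mats[[fam]]))
    sm <- apply(pca$scores, 2, lp)
    for (tg in names(vols)) {
      m <- best_matching_pc(pca, vols[[tg]], scores = sm)
      rows[[paste(fam, tg)]] <- tibble(
        subject_id = trial$subject_id, repetition = trial$repetition,
        family = fam, target = tg, pc = m$pc, rho = m$rho,
        explained = m$explained, imu = paste0("imu", 1:9),
        loading = as.vector(m$loadings)
      )
    }
  }
  bind_rows(rows)
}

#' Aggregate loadings across trials and select sensors
#'
#' Averages the absolute loading of each IMU on the retained PC across all
#' subjects and trials, per signal family and volume target, and selects
#' the (family, IMU) pairs whose mean absolute loading reaches the
#' threshold. The default threshold 0.32 corresponds to more than 10% of
#' variance shared with the PC (0.32^2 = 0.1024).
#'
#' @param matches Tibble of per-trial matches (rows as produced by
#'   [trial_pc_matches()], stacked over trials).
#' @param threshold Loading threshold.
#' @return Tibble of class `resp_selection`: `family`, `target`, `imu`,
#'   `mean_abs_loading`, `selected`.
#' @export
aggregate_and_select <- function(matches, threshold = 0.32) {
  out <- matches %>%
    group_by(.data$family, .data$target, .data$imu) %>%
    summarise(mean_abs_loading = mean(abs(.data$loading)), .groups = "drop") %>%
    mutate(selected = .data$mean_abs_loading >= threshold)
  class(out) <- c("resp_selection", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Run the sensor-selection stage over a cohort
#'
#' @param cohort A `resp_cohort` (trials are aligned on the fly if needed).
#' @param config A [resp_config()].
#' @return List: `matches` (per-trial tibble), `selection`
#'   (a `resp_selection`).
#' @export
select_sensors <- function(cohort, config = cohort$config %||% resp_config()) {
  matches <- map_dfr(cohort$trials, trial_pc_matches, config = config)
  list(matches = matches,
       selection = aggregate_and_select(matches, config$loading_threshold))
}
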