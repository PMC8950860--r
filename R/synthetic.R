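# --- torso geometry template -------------------------------------------------
#
# The supine torso is modelled as a smooth anterior surface z(x, y) over the
# marker grid: x cranial (row A at the clavicles, row G at the iliac spines),
# y lateral (midline at y = 0), z height above the bed. The baseline surface
# is a lateral dome; breathing adds two separable mode shapes (rib cage and
# abdomen), each a raised-cosine bump over its compartment's rows, zero at
# the compartment borders. All template dimensions scale isotropically with
# (body mass / 70 kg)^(1/3).

TEMPLATE <- list(
  row_pitch = 0.07,   # m, cranio-caudal node spacing
  col_pitch = 0.06,   # m, lateral node spacing
  dome_height = 0.197, # m, baseline surface height at the midline
  dome_q = 4.2         # 1/m, lateral curvature of the baseline dome
)

#' Baseline marker positions of the torso template
#'
#' @param scale Isotropic scale factor (1 = a 70 kg reference torso).
#' @return A 45 x 3 matrix (metres; columns x, y, z) with grid node rownames.
#' @export
grid_node_template <- function(scale = 1) {
  geom <- node_geometry(scale)
  pos <- cbind(x = geom$x, y = geom$y, z = geom$z0)
  rownames(pos) <- geom$node
  pos
}

# per-node geometry: baseline position, mode-shape values and slopes
node_geometry <- function(scale = 1) {
  grid <- grid_layout()
  x <- scale * TEMPLATE$row_pitch * (7 - grid$row_idx)  # G at x = 0
  y <- scale * TEMPLATE$col_pitch * (grid$col_idx - 4)
  q <- TEMPLATE$dome_q / scale
  z0 <- scale * TEMPLATE$dome_height * cos(q * y)
  dz0_dy <- -scale * TEMPLATE$dome_height * q * sin(q * y)

  x_a <- scale * TEMPLATE$row_pitch * 6  # row A
  x_e <- scale * TEMPLATE$row_pitch * 2  # row E (compartment border)
  span_rc <- x_a - x_e
  span_ab <- x_e

  u_rc <- (x_a - x) / span_rc
  in_rc <- u_rc > 0 & u_rc < 1
  phi_rc <- ifelse(in_rc, sin(pi * u_rc)^2, 0)
  dphi_rc_dx <- ifelse(in_rc, -pi * sin(2 * pi * u_rc) / span_rc, 0)

  u_ab <- (x_e - x) / span_ab
  in_ab <- u_ab > 0 & u_ab < 1
  half_w <- 3 * scale * TEMPLATE$col_pitch  # y where the lateral taper hits 0
  by <- cos(pi * y / (2 * half_w))
  dby <- -pi / (2 * half_w) * sin(pi * y / (2 * half_w))
  bx <- ifelse(in_ab, sin(pi * u_ab)^2, 0)
  dbx <- ifelse(in_ab, -pi * sin(2 * pi * u_ab) / span_ab, 0)
  phi_ab <- bx * by
  dphi_ab_dx <- dbx * by
  dphi_ab_dy <- bx * dby

  tibble(
    node = grid$node, row_idx = grid$row_idx, col_idx = grid$col_idx,
    x = x, y = y, z0 = z0, dz0_dy = dz0_dy,
    phi_rc = phi_rc, dphi_rc_dx = dphi_rc_dx,
    phi_ab = phi_ab, dphi_ab_dx = dphi_ab_dx, dphi_ab_dy = dphi_ab_dy
  )
}

# volume sensitivity (m^2): dV_c / d(mode amplitude w_c), from the prism rule;
# exact because only z moves, so projected areas are constant
mode_sensitivity <- function(mesh, geom, phi_col) {
  pos <- setNames(split(cbind(geom$x, geom$y), seq_len(nrow(geom))), geom$node)
  xx <- setNames(geom$x, geom$node)
  yy <- setNames(geom$y, geom$node)
  phi <- setNames(geom[[phi_col]], geom$node)
  area <- 0.5 * abs((xx[mesh$n2] - xx[mesh$n1]) * (yy[mesh$n3] - yy[mesh$n1]) -
                      (xx[mesh$n3] - xx[mesh$n1]) * (yy[mesh$n2] - yy[mesh$n1]))
  sum(area * (phi[mesh$n1] + phi[mesh$n2] + phi[mesh$n3]) / 3)
}

# --- subjects ----------------------------------------------------------------

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Draw subject-level parameters
#'
#' Body masses follow sex-specific normal distributions (F 57.3 +- 9.0 kg,
#' M 74.0 +- 11.4 kg), truncated below at 35 kg; heights follow the matching
#' anthropometric normals; subject breathing rates are drawn from a normal
#' distribution truncated to the configured range (default 10-18
#' breaths/min). The torso scale factor is (mass / 70)^(1/3).
#'
#' @param config A [resp_config()].
#' @param n Number of subjects; default `config$n_female + config$n_male`.
#' @param sex Optional vector (or single value, recycled) of `"F"`/`"M"`;
#'   default: `n_female` females followed by `n_male` males.
#' @return A tibble: `subject_id`, `sex`, `body_mass` (kg), `height` (m),
#'   `rr` (breaths/min), `torso_scale`.
#' @export
generate_subject_params <- function(config = resp_config(), n = NULL, sex = NULL) {
  if (is.null(sex)) {
    sex <- c(rep("F", config$n_female), rep("M", config$n_male))
  }
  if (!is.null(n)) sex <- rep_len(sex, n)
  n <- length(sex)
  f <- sex == "F"
  mass <- numeric(n)
  mass[f] <- rtruncnorm(sum(f), config$mass_mean_f, config$mass_sd_f, lower = 35)
  mass[!f] <- rtruncnorm(sum(!f), config$mass_mean_m, config$mass_sd_m, lower = 35)
  height <- numeric(n)
  height[f] <- rnorm(sum(f), config$height_mean_f, config$height_sd_f)
  height[!f] <- rnorm(sum(!f), config$height_mean_m, config$height_sd_m)
  rr <- rtruncnorm(n, config$rr_mean, config$rr_sd,
                   lower = config$rr_range[1], upper = config$rr_range[2])
  tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = sex, body_mass = mass, height = height, rr = rr,
    torso_scale = (mass / 70)^(1 / 3)
  )
}

# --- breathing waveform ------------------------------------------------------

# cycle list covering [t_from, t_to]: onset time, period, amplitude factor
draw_cycles <- function(rr, t_from, t_to, cv_rate, cv_amp) {
  T0 <- 60 / rr
  t <- t_from
  onset <- period <- ampf <- numeric(0)
  while (t < t_to) {
    Tk <- T0 * max(0.5, 1 + rnorm(1, 0, cv_rate))
    onset <- c(onset, t)
    period <- c(period, Tk)
    ampf <- c(ampf, max(0.2, 1 + rnorm(1, 0, cv_amp)))
    t <- t + Tk
  }
  tibble(onset = onset, period = period, ampf = ampf)
}

# unwrapped phase (rad) and smoothed amplitude factor at arbitrary times
cycle_phase <- function(cycles, times) {
  k <- findInterval(times, cycles$onset, rightmost.closed = FALSE)
  k[k < 1] <- 1
  theta <- 2 * pi * ((k - 1) + (times - cycles$onset[k]) / cycles$period[k])
  mid <- cycles$onset + cycles$period / 2
  ampf <- stats::approx(mid, cycles$ampf, xout = times, rule = 2)$y
  list(theta = theta, ampf = ampf)
}

# waveform shape over one cycle: fundamental plus a small second harmonic
# (h2 > 0 shortens inhalation relative to exhalation); minimum near theta = 0
breath_shape <- function(theta, h2) -cos(theta) - h2 * sin(2 * theta)

# extrema of an arbitrary single-cycle shape, by dense evaluation
shape_cycle_stats <- function(f) {
  th <- seq(-pi / 2, 3 * pi / 2, length.out = 20001)
  v <- f(th)
  i_min <- which.min(v); i_max <- which.max(v)
  list(theta_min = th[i_min], theta_max = th[i_max],
       v_min = v[i_min], v_max = v[i_max])
}

# --- trial generation --------------------------------------------------------

imu_channel_names <- function() {
  as.vector(t(outer(paste0("imu", 1:9), c("ax", "ay", "az", "gx", "gy", "gz"),
                    paste, sep = "_")))
}

central_diff2 <- function(x, rate) {
  n <- length(x)
  d2 <- c(0, diff(x, differences = 2), 0) * rate^2
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  d2
}

#' Generate one synthetic supine-breathing trial
#'
#' Builds a trial (markers at the marker rate, IMU streams at the IMU rate)
#' plus its ground truth. Grid-node vertical displacement is
#' `baseline + w_RC(t) phi_RC + w_AB(t) phi_AB`, with the compartmental
#' waveforms scaled so that plethysmography on the noise-free markers
#' reproduces the target tidal excursions exactly. Each IMU reads the
#' specific force of its node (gravity plus the node's vertical inertial
#' acceleration, expressed in the tilting sensor frame) plus white noise;
#' gyroscopes read the surface tilt rate plus noise. Quasi-impulsive tap
#' pulses are injected at the IMU-1 node in both streams, and an unknown
#' clock offset (uniform, default +-1 s) separates the two streams.
#'
#' @param subject One-row subject tibble (see [generate_subject_params()]).
#' @param config A [resp_config()]; cohort keys control waveform, noise and
#'   tap parameters.
#' @param repetition Repetition index stored in the trial.
#' @param seed Optional seed for this trial alone.
#' @return List with elements `trial` (class `resp_trial`) and `truth`
#'   (class `resp_truth`: noise-free `volumes` at the IMU rate in absolute
#'   time, per-compartment respiratory `params`, the `clock_offset`, and the
#'   per-cycle table).
#' @export
generate_trial <- function(subject, config = resp_config(), repetition = 1L,
                           seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trial(subject, config, repetition)))
  }
  duration <- config$duration
  if (duration < 30) abort("Trial duration must be at least 30 s.")
  scale <- subject$torso_scale
  geom <- node_geometry(scale)
  mesh <- build_grid_mesh()

  s_rc <- mode_sensitivity(mesh, geom, "phi_rc")   # m^2
  s_ab <- mode_sensitivity(mesh, geom, "phi_ab")

  amp_cw <- config$tidal_per_kg * subject$body_mass        # L, peak-to-peak
  amp_ab <- config$ab_fraction * amp_cw
  amp_rc <- amp_cw - amp_ab
  h2 <- config$second_harmonic
  delta <- config$phase_shift                              # RC lags AB

  cycles <- draw_cycles(subject$rr, -2, duration + 2,
                        config$rate_jitter_cv, config$amp_jitter_cv)
  offset <- runif(1, config$clock_offset_range[1], config$clock_offset_range[2])

  t_mark <- seq(0, duration, by = 1 / config$marker_rate)
  t_imu_own <- seq(0, duration, by = 1 / config$imu_rate)
  t_imu <- t_imu_own + offset  # absolute time of IMU samples

  # compartmental volume waveforms (L, about 0) and mode amplitudes (m)
  vol_wave <- function(times, amp, phase) {
    cp <- cycle_phase(cycles, times)
    0.5 * amp * cp$ampf * breath_shape(cp$theta - phase, h2)
  }
  w_of <- function(times) {
    list(
      rc = vol_wave(times, amp_rc, delta) / (1000 * s_rc),
      ab = vol_wave(times, amp_ab, 0) / (1000 * s_ab)
    )
  }

  # tilt sanity check at the IMU nodes over one cycle of extreme amplitude
  imu_geom <- geom[match(imu_node_map(), geom$node), ]
  w_max_rc <- 0.5 * amp_rc * max(cycles$ampf) * (1 + abs(h2)) / (1000 * s_rc)
  w_max_ab <- 0.5 * amp_ab * max(cycles$ampf) * (1 + abs(h2)) / (1000 * s_ab)
  sx_max <- abs(w_max_rc * imu_geom$dphi_rc_dx) + abs(w_max_ab * imu_geom$dphi_ab_dx)
  sy_max <- abs(imu_geom$dz0_dy) + abs(w_max_ab * imu_geom$dphi_ab_dy)
  tilt <- atan(sqrt(sx_max^2 + sy_max^2)) * 180 / pi
  if (any(tilt > config$max_tilt_deg)) {
    abort(sprintf(
      "Tidal amplitude incompatible with geometry: IMU tilt reaches %.1f deg (limit %g).",
      max(tilt), config$max_tilt_deg))
  }

  # tap pulses on the IMU-1 node (absolute times within the first ~4 s)
  tap_times <- 1 + (seq_len(config$n_taps) - 1) * 1.2 +
    runif(config$n_taps, -0.15, 0.15)
  tap_amp_m <- config$tap_amplitude / 1000
  tap_disp <- function(times) {
    out <- numeric(length(times))
    for (t0 in tap_times) {
      u <- (times - t0) / config$tap_width
      in_p <- u >= 0 & u <= 1
      out[in_p] <- out[in_p] + tap_amp_m * 0.5 * (1 - cos(2 * pi * u[in_p]))
    }
    out
  }
  tap_acc <- function(times) {
    out <- numeric(length(times))
    for (t0 in tap_times) {
      u <- (times - t0) / config$tap_width
      in_p <- u >= 0 & u <= 1
      out[in_p] <- out[in_p] +
        tap_amp_m * 0.5 * (2 * pi / config$tap_width)^2 * cos(2 * pi * u[in_p])
    }
    out
  }

  # ---- marker stream (mm, marker clock = absolute time) ----
  wm <- w_of(t_mark)
  n_m <- length(t_mark)
  markers <- tibble(time = t_mark)
  tap_node <- imu_node_map()[["imu1"]]
  for (i in seq_len(nrow(geom))) {
    nd <- geom$node[i]
    z <- geom$z0[i] + wm$rc * geom$phi_rc[i] + wm$ab * geom$phi_ab[i]
    if (nd == tap_node) z <- z + tap_disp(t_mark)
    markers[[paste0(nd, "_X")]] <- 1000 * geom$x[i] +
      rnorm(n_m, 0, config$marker_noise_sd)
    markers[[paste0(nd, "_Y")]] <- 1000 * geom$y[i] +
      rnorm(n_m, 0, config$marker_noise_sd)
    markers[[paste0(nd, "_Z")]] <- 1000 * z +
      rnorm(n_m, 0, config$marker_noise_sd)
  }
  if (config$dropout_prob > 0) {
    droppable <- which(t_mark > 0.5 & t_mark < duration - 0.5)
    for (nd in geom$node) {
      drop <- droppable[runif(length(droppable)) < config$dropout_prob]
      if (length(drop)) {
        for (ax in c("_X", "_Y", "_Z")) markers[[paste0(nd, ax)]][drop] <- NA_real_
      }
    }
  }
  attr(markers, "rate") <- config$marker_rate

  # ---- IMU streams (SI units, IMU clock; phenomena sampled at t_imu) ----
  wi <- w_of(t_imu)
  ddw_rc <- central_diff2(wi$rc, config$imu_rate)
  ddw_ab <- central_diff2(wi$ab, config$imu_rate)
  n_i <- length(t_imu)
  imus <- tibble(time = t_imu_own)
  for (j in seq_len(9)) {
    gi <- imu_geom[j, ]
    s_x <- wi$rc * gi$dphi_rc_dx + wi$ab * gi$dphi_ab_dx
    s_y <- gi$dz0_dy + wi$ab * gi$dphi_ab_dy
    zdd <- ddw_rc * gi$phi_rc + ddw_ab * gi$phi_ab
    if (j == 1L) zdd <- zdd + tap_acc(t_imu)
    # sensor axes in the lab frame: z along the surface normal, x the
    # cranial direction projected onto the surface, y completing right-handed
    nn <- sqrt(1 + s_x^2 + s_y^2)
    nx <- -s_x / nn; ny <- -s_y / nn; nz <- 1 / nn
    xs_x <- 1 - nx * nx; xs_y <- -nx * ny; xs_z <- -nx * nz
    xn <- sqrt(xs_x^2 + xs_y^2 + xs_z^2)
    xs_x <- xs_x / xn; xs_y <- xs_y / xn; xs_z <- xs_z / xn
    ys_x <- ny * xs_z - nz * xs_y
    ys_y <- nz * xs_x - nx * xs_z
    ys_z <- nx * xs_y - ny * xs_x
    f <- GRAVITY + zdd  # vertical specific force (lab frame)
    imus[[paste0("imu", j, "_ax")]] <- f * xs_z + rnorm(n_i, 0, config$accel_noise_sd)
    imus[[paste0("imu", j, "_ay")]] <- f * ys_z + rnorm(n_i, 0, config$accel_noise_sd)
    imus[[paste0("imu", j, "_az")]] <- f * nz + rnorm(n_i, 0, config$accel_noise_sd)
    roll <- -atan(s_y)   # about the cranial axis
    pitch <- atan(s_x)   # about the lateral axis
    imus[[paste0("imu", j, "_gx")]] <- c(0, diff(roll)) * config$imu_rate +
      rnorm(n_i, 0, config$gyro_noise_sd)
    imus[[paste0("imu", j, "_gy")]] <- c(0, diff(pitch)) * config$imu_rate +
      rnorm(n_i, 0, config$gyro_noise_sd)
    imus[[paste0("imu", j, "_gz")]] <- rnorm(n_i, 0, config$gyro_noise_sd)
  }
  attr(imus, "rate") <- config$imu_rate

  trial <- new_trial(
    subject_id = subject$subject_id, repetition = as.integer(repetition),
    sex = subject$sex, body_mass = subject$body_mass, height = subject$height,
    markers = markers, imus = imus,
    marker_rate = config$marker_rate, imu_rate = config$imu_rate
  )

  # ---- ground truth ----
  t_truth <- seq(0, duration, by = 1 / config$imu_rate)
  base <- frame_volume(mesh, grid_node_template(scale))
  truth_vol <- tibble(
    time = t_truth,
    V_RC = base[["RC"]] + vol_wave(t_truth, amp_rc, delta),
    V_AB = base[["AB"]] + vol_wave(t_truth, amp_ab, 0)
  )
  truth_vol$V_CW <- truth_vol$V_RC + truth_vol$V_AB
  truth_vol <- truth_vol[, c("time", "V_CW", "V_RC", "V_AB")]
  attr(truth_vol, "rate") <- config$imu_rate
  class(truth_vol) <- c("resp_volumes", class(truth_vol))

  truth_params <- true_parameters(cycles, amp_rc, amp_ab, h2, delta,
                                  window = c(config$sync_window, duration))
  truth <- structure(
    list(volumes = truth_vol, params = truth_params,
         clock_offset = offset, cycles = cycles, tap_times = tap_times),
    class = "resp_truth"
  )
  list(trial = trial, truth = truth)
}

# analytic per-compartment respiratory parameters over complete cycles inside
# the analysis window
true_parameters <- function(cycles, amp_rc, amp_ab, h2, delta, window) {
  shapes <- list(
    CW = function(th) 0.5 * amp_rc * breath_shape(th - delta, h2) +
      0.5 * amp_ab * breath_shape(th, h2),
    RC = function(th) 0.5 * amp_rc * breath_shape(th - delta, h2),
    AB = function(th) 0.5 * amp_ab * breath_shape(th, h2)
  )
  keep <- cycles$onset >= window[1] & cycles$onset + cycles$period <= window[2]
  cc <- cycles[keep, ]
  out <- imap(shapes, function(f, comp) {
    st <- shape_cycle_stats(f)
    di_frac <- (st$theta_max - st$theta_min) / (2 * pi)
    vi <- cc$ampf * (st$v_max - st$v_min)
    tibble(
      compartment = comp,
      RR = 60 / mean(cc$period),
      DI = mean(cc$period * di_frac),
      DE = mean(cc$period * (1 - di_frac)),
      VI = mean(vi), VE = mean(vi),
      cycles = nrow(cc)
    )
  })
  bind_rows(out)
}

new_trial <- function(subject_id, repetition, sex, body_mass, height,
                      markers, imus, marker_rate, imu_rate) {
  stopifnot(repetition %in% c(1L, 2L), body_mass > 0)
  structure(
    list(subject_id = subject_id, repetition = repetition, sex = sex,
         body_mass = body_mass, height = height,
         markers = markers, imus = imus,
         marker_rate = marker_rate, imu_rate = imu_rate,
         aligned = FALSE),
    class = "resp_trial"
  )
}

#' @export
print.resp_trial <- function(x, ...) {
  cat(sprintf(
    "<resp_trial> %s rep %d (%s, %.1f kg)%s\n  markers: %d frames @ %g Hz; IMUs: %d samples @ %g Hz\n",
    x$subject_id, x$repetition, x$sex, x$body_mass,
    if (isTRUE(x$aligned)) " [aligned]" else "",
    nrow(x$markers), attr(x$markers, "rate") %||% x$marker_rate,
    nrow(x$imus), x$imu_rate
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort
#'
#' Draws the subjects (default 7 females + 11 males) and generates
#' `n_repetitions` trials per subject (default 2, for 36 trials).
#' Subject-level parameters are shared across repetitions; cycle-level
#' waveform jitter, noise, taps and clock offsets are independent per trial.
#' All randomness derives from `config$seed`, so equal configurations yield
#' identical cohorts.
#'
#' @param config A [resp_config()].
#' @return A list of class `resp_cohort`: `subjects` (tibble), `trials`
#'   (list of `resp_trial`), `truths` (list of `resp_truth`, parallel to
#'   `trials`), and `config`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(resp_config(seed = 1, n_female = 1, n_male = 1,
#'                                       n_repetitions = 1, duration = 40))
#' length(cohort$trials)
#' }
#' @export
generate_cohort <- function(config = resp_config()) {
  withr::with_seed(config$seed, {
    subjects <- generate_subject_params(config)
    trials <- list(); truths <- list()
    for (i in seq_len(nrow(subjects))) {
      for (rep_i in seq_len(config$n_repetitions)) {
        g <- generate_trial(subjects[i, ], config, repetition = rep_i)
        key <- paste0(subjects$subject_id[i], "_r", rep_i)
        trials[[key]] <- g$trial
        truths[[key]] <- g$truth
      }
    }
    structure(list(subjects = subjects, trials = trials, truths = truths,
                   config = config),
              class = "resp_cohort")
  })
}

#' @export
print.resp_cohort <- function(x, ...) {
  cat(sprintf("<resp_cohort> %d subjects (%d F, %d M), %d trials of %g s\n",
              nrow(x$subjects), sum(x$subjects$sex == "F"),
              sum(x$subjects$sex == "M"), length(x$trials),
              x$config$duration))
  invisible(x)
}

#' Tiny fixture cohort for examples and tests
#'
#' A reduced cohort (default 3 subjects, one repetition, 45 s trials) small
#' enough to run the full pipeline in seconds.
#'
#' @param n_female,n_male,n_repetitions,duration Cohort shape overrides.
#' @param seed Seed.
#' @param ... Further [resp_config()] overrides.
#' @return A `resp_cohort`.
#' @export
fixture_cohort <- function(n_female = 1, n_male = 2, n_repetitions = 1,
                           duration = 45, seed = 1L, ...) {
  generate_cohort(resp_config(
    seed = seed, n_female = n_female, n_male = n_male,
    n_repetitions = n_repetitions, duration = duration, ...
  ))
}
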