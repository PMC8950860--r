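#' Analysis configuration
#'
#' Central container for the tunable parameters of the pipeline. Defaults
#' reproduce the reference protocol: markers digitised at 50 Hz, IMUs at
#' 100 Hz, a 10 Hz zero-lag 4th-order Butterworth pre-filter on all channels,
#' a 2.5 Hz filter plus demeaning before modelling, and a 0.32 absolute
#' loading threshold for sensor selection (0.32^2 > 10% shared variance).
#'
#' @param marker_rate Marker sampling rate (Hz).
#' @param imu_rate IMU sampling rate (Hz); markers are spline-upsampled to
#'   this rate before time alignment.
#' @param prefilter_cutoff Low-pass cut-off (Hz) applied to every marker and
#'   IMU channel during preprocessing.
#' @param model_cutoff Low-pass cut-off (Hz) applied to volumes and selected
#'   IMU signals before correlation/regression; signals are demeaned after
#'   this filter.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is squared).
#' @param loading_threshold Minimum mean absolute PC loading for a
#'   (signal family, IMU) pair to be selected.
#' @param sync_window Length (s) of the initial window containing the
#'   synchronisation taps; it is searched for the cross-correlation peak and
#'   then discarded from the analysis segment.
#' @param max_gap Longest marker gap (s) that gap filling will interpolate.
#' @param peak_prominence_sd Minimum extremum prominence, as a fraction of
#'   the channel SD, for breath segmentation (0 disables the guard).
#' @param peak_min_distance Minimum separation (s) between same-type breath
#'   extrema (0 disables the guard).
#' @param rr_from Either `"period"` (respiratory rate = 60 / mean min-to-min
#'   period; default) or `"count"` (cycle count divided by elapsed time).
#' @param seed Integer seed controlling every random draw of the synthetic
#'   generator.
#' @param ... Overrides for synthetic-cohort parameters; see
#'   [cohort_defaults()] for names and units.
#'
#' @return A named list of class `resp_config`.
#' @examples
#' cfg <- resp_config(seed = 7)
#' cfg$model_cutoff
#' @export
resp_config <- function(marker_rate = 50,
                        imu_rate = 100,
                        prefilter_cutoff = 10,
                        model_cutoff = 2.5,
                        filter_order = 4,
                        loading_threshold = 0.32,
                        sync_window = 6,
                        max_gap = 0.5,
                        peak_prominence_sd = 0.2,
                        peak_min_distance = 1.0,
                        rr_from = c("period", "count"),
                        seed = 1L,
                        ...) {
  rr_from <- match.arg(rr_from)
  cfg <- c(
    list(
      marker_rate = marker_rate, imu_rate = imu_rate,
      prefilter_cutoff = prefilter_cutoff, model_cutoff = model_cutoff,
      filter_order = as.integer(filter_order),
      loading_threshold = loading_threshold,
      sync_window = sync_window, max_gap = max_gap,
      peak_prominence_sd = peak_prominence_sd,
      peak_min_distance = peak_min_distance,
      rr_from = rr_from, seed = as.integer(seed)
    ),
    cohort_defaults()
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      abort(paste0(
        "Unknown configuration key(s): ", paste(unknown, collapse = ", ")
      ))
    }
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "resp_config"
  validate_config(cfg)
  cfg
}

#' Synthetic-cohort default parameters
#'
#' Defaults used by [generate_cohort()] and [generate_trial()]. They encode
#' the study conditions the generator emulates: 18 subjects (7 F, 11 M), two
#' ~2-minute supine quiet-breathing repetitions each, sex-specific body-mass
#' distributions, near-sinusoidal compartmental breathing at 10-18
#' breaths/min, and instrument noise typical of optical marker tracking and
#' consumer inertial sensors.
#'
#' @return Named list of generator parameters (units in the names' docs):
#' \describe{
#'   \item{n_female, n_male, n_repetitions}{cohort composition}
#'   \item{duration}{trial length (s)}
#'   \item{mass_mean_f, mass_sd_f, mass_mean_m, mass_sd_m}{body mass (kg)}
#'   \item{height_mean_f, height_sd_f, height_mean_m, height_sd_m}{height (m)}
#'   \item{rr_mean, rr_sd, rr_range}{subject breathing rate (breaths/min):
#'     normal draw truncated to `rr_range`}
#'   \item{tidal_per_kg}{chest-wall peak-to-peak tidal excursion (L/kg)}
#'   \item{ab_fraction}{abdominal share of the chest-wall tidal volume}
#'   \item{phase_shift}{rib-cage lag behind the abdomen (rad)}
#'   \item{second_harmonic}{relative amplitude of the waveform's second
#'     harmonic (controls inhalation/exhalation asymmetry)}
#'   \item{rate_jitter_cv, amp_jitter_cv}{cycle-to-cycle coefficients of
#'     variation of period and amplitude}
#'   \item{accel_noise_sd}{accelerometer white noise SD per sample (m/s^2)}
#'   \item{gyro_noise_sd}{gyroscope white noise SD per sample (rad/s)}
#'   \item{marker_noise_sd}{marker coordinate noise SD (mm)}
#'   \item{dropout_prob}{per-frame marker dropout probability}
#'   \item{n_taps, tap_amplitude, tap_width}{synchronisation taps on IMU 1:
#'     count, marker pulse amplitude (mm) and half-cosine width (s)}
#'   \item{clock_offset_range}{uniform range (s) of the unknown IMU-vs-camera
#'     clock offset}
#'   \item{max_tilt_deg}{geometric sanity limit on IMU tilt}
#' }
#' @export
cohort_defaults <- function() {
  list(
    n_female = 7L, n_male = 11L, n_repetitions = 2L, duration = 120,
    mass_mean_f = 57.3, mass_sd_f = 9.0,
    mass_mean_m = 74.0, mass_sd_m = 11.4,
    height_mean_f = 1.66, height_sd_f = 0.05,
    height_mean_m = 1.76, height_sd_m = 0.06,
    rr_mean = 14, rr_sd = 2, rr_range = c(10, 18),
    tidal_per_kg = 0.0083, ab_fraction = 0.6,
    phase_shift = 0.2, second_harmonic = 0.04,
    rate_jitter_cv = 0.03, amp_jitter_cv = 0.05,
    accel_noise_sd = 0.0085, gyro_noise_sd = 0.01,
    marker_noise_sd = 0.3, dropout_prob = 5e-4,
    n_taps = 3L, tap_amplitude = 6, tap_width = 0.12,
    clock_offset_range = c(-1, 1),
    max_tilt_deg = 30
  )
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$marker_rate > 0, cfg$imu_rate >= cfg$marker_rate,
    cfg$filter_order >= 1, cfg$sync_window > 0, cfg$max_gap > 0,
    cfg$loading_threshold >= 0, cfg$loading_threshold <= 1
  )
  if (!(cfg$model_cutoff > 0 &&
          cfg$model_cutoff < cfg$prefilter_cutoff &&
          cfg$prefilter_cutoff < cfg$imu_rate / 2)) {
    abort("Required: 0 < model_cutoff < prefilter_cutoff < imu_rate/2.")
  }
  invisible(cfg)
}

#' @export
print.resp_config <- function(x, ...) {
  cat("<resp_config>\n")
  cat(sprintf("  rates: markers %g Hz, IMUs %g Hz\n", x$marker_rate, x$imu_rate))
  cat(sprintf("  filters: pre %g Hz, model %g Hz (Butterworth order %d, zero-lag)\n",
              x$prefilter_cutoff, x$model_cutoff, x$filter_order))
  cat(sprintf("  selection threshold: |loading| >= %g\n", x$loading_threshold))
  cat(sprintf("  sync window: %g s; seed: %d\n", x$sync_window, x$seed))
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values are coerced to numeric where possible; two-element ranges
#' may be written as comma-separated pairs. Unknown keys are an error so that
#' typos in thresholds are caught rather than silently ignored.
#'
#' @param path Path to the configuration file.
#' @return A `resp_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) abort(paste0("Cannot parse config line: '", ln, "'"))
    val <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    kv[[m[2]]] <- if (!anyNA(num)) num else val
  }
  do.call(resp_config, kv)
}
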